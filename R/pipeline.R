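#' @title End-to-end pipeline and batch entry points
#' @description Ties the stages together: per-image segmentation
#'   (vessels -> inpainting -> localization -> disc level set -> cup
#'   cascade -> region parameters), batch simulation of phantom datasets,
#'   and batch evaluation of marking tables. Every stochastic operation
#'   receives an explicit seed derived from the run configuration, so fixed
#'   config plus seed gives identical outputs. A thin command-line wrapper
#'   around these functions ships in `inst/cli/fundus-cdr`.
#' @name pipeline
NULL

#' Default run configuration
#'
#' One canonical list of every pipeline constant: quality profile, vessel
#' extraction, disc localization/level set, cup cascade, evaluation
#' thresholds and the master seed. Values can be overridden piecemeal via a
#' YAML file ([load_config()]) or by editing the returned list.
#'
#' @param seed master seed.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    profile = "high_quality",
    vessel = list(radius = NULL, threshold_rule = "otsu",
                  fixed_threshold = 10, iterations = 100),
    disc = list(k_localize = 2, roi_fraction = 0.25, min_component = 5e-4,
                init_fraction = 0.7, fou_width = 10,
                ls = list(dt = 1, iterations = 400, mu = 0.2, lambda = 5,
                          alpha = -1.8, sigma = 2, tol = 1e-3)),
    cup = list(min_spot = 50, closing_radius = 5, area_floor = 3000,
               area_floor_frame_width = 2376, scale_area_floor = TRUE,
               hough_range = c(0.15, 0.6), fou_width = 10,
               area_test_after_hough = TRUE),
    de = list(pop_size = 30, generations = 100, F = 0.5, CR = 0.9),
    simulate = list(profile = "small", n_images = 20, noise_sigma = 8,
                    blur_sigma = 1.5, n_vessels = 6,
                    cdr_range = c(0.35, 0.7),
                    grader = list(n_graders = 6, area_jitter_cv = 0.05,
                                  centroid_jitter_sd = 2, cdr_jitter_sd = 0.03,
                                  outlier_rate = 0, outlier_scale = 5)),
    evaluate = list(override_cdr = 0.075, thresholds = NULL)
  )
}

# Recursively merge an override list into the defaults.
merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a YAML run configuration
#'
#' Reads a YAML file of overrides and merges it into [default_config()].
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param seed master seed (overridden by a `seed` key in the file).
#' @return configuration list.
#' @export
load_config <- function(path = NULL, seed = 1L) {
  cfg <- default_config(seed)
  if (!is.null(path)) cfg <- merge_config(cfg, yaml::read_yaml(path))
  cfg
}

config_disc <- function(cfg) {
  disc_config(vessel = vessel_params(radius = cfg$vessel$radius,
                                     threshold_rule = cfg$vessel$threshold_rule,
                                     fixed_threshold = cfg$vessel$fixed_threshold,
                                     iterations = cfg$vessel$iterations),
              ls = do.call(level_set_params, cfg$disc$ls),
              k_localize = cfg$disc$k_localize,
              roi_fraction = cfg$disc$roi_fraction,
              min_component = cfg$disc$min_component,
              init_fraction = cfg$disc$init_fraction,
              fou_width = cfg$disc$fou_width,
              seed = sub_seed(cfg$seed, 11))
}

config_cup <- function(cfg) {
  cup_config(min_spot = cfg$cup$min_spot,
             closing_radius = cfg$cup$closing_radius,
             area_floor = cfg$cup$area_floor,
             area_floor_frame_width = cfg$cup$area_floor_frame_width,
             scale_area_floor = cfg$cup$scale_area_floor,
             hough_range = cfg$cup$hough_range,
             fou_width = cfg$cup$fou_width,
             area_test_after_hough = cfg$cup$area_test_after_hough,
             seed = sub_seed(cfg$seed, 22))
}

#' Segment one fundus image end to end
#'
#' @param image a [fundus_image()].
#' @param config configuration list from [default_config()]/[load_config()].
#' @return list with `status` (`"ok"`, `"not_localized"` or `"cup_failed"`),
#'   `disc` (a `disc_result`), `cup` (a `cup_result` or `NULL`), `params`
#'   (a [region_params()] or `NULL`), and `log` (cup cascade decisions).
#' @export
segment_fundus <- function(image, config = default_config()) {
  dres <- segment_disc(image, config_disc(config))
  if (!dres$localized)
    return(list(status = "not_localized", disc = dres, cup = NULL,
                params = NULL, log = NULL))
  roi <- dres$roi
  roi_gray <- roi_crop(dres$inpainted_green, roi)
  disc_roi <- roi_crop(dres$mask, roi)
  vess_roi <- roi_crop(dres$vessels, roi)
  cres <- segment_cup(roi_gray, disc_roi, vess_roi, config_cup(config),
                      image_width = image$width)
  if (!cres$success)
    return(list(status = "cup_failed", disc = dres, cup = cres,
                params = NULL, log = cres$log))
  cup_full <- roi_uncrop(cres$mask, roi, image$height, image$width)
  list(status = "ok", disc = dres, cup = cres,
       params = region_params_from_masks(dres$mask, cup_full),
       log = cres$log)
}

#' Simulate a phantom dataset on disk
#'
#' Writes phantom images and truth masks (PNG), the ground-truth parameter
#' table, simulated grader markings and the injected-outlier ledger (CSV),
#' plus a JSON manifest recording every seed. Re-running with the same
#' configuration reproduces the files bit for bit.
#'
#' @param config configuration list; `config$simulate` controls the phantom
#'   and grader settings.
#' @param out_dir output directory (created if needed).
#' @param n number of images (default from config).
#' @return the manifest list, invisibly.
#' @export
run_simulate <- function(config = default_config(), out_dir, n = NULL) {
  sc <- config$simulate
  n <- n %||% sc$n_images
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  size <- phantom_profile(sc$profile)
  truth_rows <- list()
  entries <- list()
  for (i in seq_len(n)) {
    seed_i <- sub_seed(config$seed, 1000 + i)
    cdr <- withr::with_seed(seed_i,
      stats::runif(2, sc$cdr_range[1], sc$cdr_range[2]))
    spec <- phantom_spec(size = size, cdr_h = cdr[1], cdr_v = cdr[2],
                         noise_sigma = sc$noise_sigma,
                         blur_sigma = sc$blur_sigma,
                         n_vessels = sc$n_vessels, seed = seed_i)
    ph <- generate_phantom(spec)
    id <- sprintf("phantom_%03d", i)
    write_image(ph$image, file.path(out_dir, paste0(id, ".png")))
    write_mask(ph$disc, file.path(out_dir, paste0(id, "_disc.png")))
    write_mask(ph$cup, file.path(out_dir, paste0(id, "_cup.png")))
    write_mask(ph$vessels, file.path(out_dir, paste0(id, "_vessels.png")))
    truth_rows[[i]] <- params_row(id, "truth", ph$truth)
    entries[[i]] <- list(image_id = id, seed = seed_i,
                         cdr_h = cdr[1], cdr_v = cdr[2])
  }
  gspec <- do.call(grader_sim_spec,
                   c(sc$grader, list(seed = sub_seed(config$seed, 2000))))
  if (n > 0) {
    truth <- do.call(rbind, truth_rows)
    utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    sim <- simulate_markings(truth, gspec)
    write_markings(sim$markings, file.path(out_dir, "markings.csv"))
    utils::write.csv(sim$outliers, file.path(out_dir, "outliers.csv"),
                     row.names = FALSE)
  }
  manifest <- list(n_images = n, profile = sc$profile, seed = config$seed,
                   grader_seed = gspec$seed, images = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Segment a batch of images
#'
#' Continues on per-image errors; a structured log line per image records
#' the status, the level-set path and the accepted cup loop.
#'
#' @param config configuration list.
#' @param paths character vector of image paths, or a list of
#'   [fundus_image()] objects (named by image id).
#' @param out_csv optional path for the algorithm marking table.
#' @return data.frame with one row per image: `image_id`, `status`,
#'   `path_used`, `loop_used`, plus the region-parameter columns (NA on
#'   failure).
#' @export
run_segment <- function(config = default_config(), paths, out_csv = NULL) {
  items <- if (is.character(paths)) {
    stats::setNames(as.list(paths), sub("\\.[^.]+$", "", basename(paths)))
  } else paths
  rows <- list()
  for (id in names(items)) {
    res <- tryCatch({
      img <- items[[id]]
      if (is.character(img)) img <- read_image(img, profile = config$profile)
      segment_fundus(img, config)
    }, error = function(e) {
      message(sprintf("image=%s status=error msg=%s", id, conditionMessage(e)))
      list(status = "error", disc = NULL, cup = NULL, params = NULL)
    })
    rp <- res$params
    row <- data.frame(image_id = id, status = res$status,
                      path_used = res$disc$path_used %||% NA_character_,
                      loop_used = if (!is.null(res$cup)) res$cup$loop_used else NA_integer_,
                      stringsAsFactors = FALSE)
    prow <- if (!is.null(rp)) params_row(id, "algorithm", rp)[, -(1:2)] else
      params_row(id, "algorithm",
                 region_params(0, c(NA, NA), 0, c(NA, NA), NA, NA))[, -(1:2)]
    rows[[id]] <- cbind(row, prow)
    message(sprintf("image=%s status=%s path=%s loop=%s", id, res$status,
                    row$path_used, row$loop_used))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  if (all(out$status == "error")) stopf("all images failed")
  out
}

#' Evaluate a marking table
#'
#' Produces accuracy tables and agreement matrices for the HCDR, VCDR and
#' final (all-parameter) analyses.
#'
#' @param config configuration list.
#' @param markings marking table data.frame or CSV path (manual graders plus
#'   optional algorithm rows).
#' @param not_localized image ids excluded as localization failures.
#' @param out_dir optional directory for CSV reports.
#' @return named list: per analysis, `accuracy` (data.frame) and `agreement`
#'   (matrix).
#' @export
run_evaluate <- function(config = default_config(), markings,
                         not_localized = character(0), out_dir = NULL) {
  if (is.character(markings)) markings <- read_markings(markings)
  markings <- validate_markings(markings)
  graders <- setdiff(unique(markings$grader_id), "algorithm")
  if (length(graders) < 6)
    stopf("need 6 manual graders; missing: %s",
          paste(setdiff(as.character(1:6), graders), collapse = ", "))
  thr <- sd_thresholds(markings, override_cdr = config$evaluate$override_cdr)
  fixed <- config$evaluate$thresholds
  if (!is.null(fixed))
    for (p in names(fixed)) if (!is.na(fixed[[p]])) thr[[p]] <- fixed[[p]]
  out <- list()
  for (an in c("hcdr", "vcdr", "final")) {
    acc <- accuracy_table(markings, thr, an, not_localized)
    agr <- agreement_matrix(markings, thr, an, not_localized)
    out[[an]] <- list(accuracy = acc, agreement = agr)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(acc, file.path(out_dir, paste0("accuracy_", an, ".csv")))
      ag <- rbind(agr, total = attr(agr, "totals"))
      utils::write.csv(ag, file.path(out_dir, paste0("agreement_", an, ".csv")))
    }
  }
  out
}
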