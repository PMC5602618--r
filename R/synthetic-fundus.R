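#' @title Synthetic fundus phantoms and simulated grader markings
#' @description Generates phantom fundus images with a bright elliptical
#'   optic disc containing a brighter elliptical cup, dark curvilinear
#'   vessels, background vignetting, blur and noise -- with exact ground-truth
#'   masks -- plus simulated multi-grader marking tables with controllable
#'   jitter and injected outliers. These phantoms stand in for clinical
#'   datasets in all tests; they are synthetic and make no claim of
#'   photorealism.
#' @name synthetic-fundus
NULL

#' Built-in phantom canvas profiles
#'
#' Three profiles mimic the frame sizes of common fundus camera families
#' (2240x1488, 2376x1584, 2743x1936) and a small 512x512 profile keeps test
#' suites fast.
#'
#' @param name one of `"small"`, `"messidor"`, `"binrushed"`, `"magrabi"`.
#' @return integer vector `c(height, width)`.
#' @export
phantom_profile <- function(name = c("small", "messidor", "binrushed", "magrabi")) {
  switch(match.arg(name),
         small     = c(512L, 512L),
         messidor  = c(1488L, 2240L),
         binrushed = c(1584L, 2376L),
         magrabi   = c(1936L, 2743L))
}

#' Specify a fundus phantom
#'
#' Geometry is an ellipse-in-ellipse model: the cup semi-axes are
#' `cdr_v * disc_axes[1]` (vertical) and `cdr_h * disc_axes[2]` (horizontal),
#' concentric with the disc, so the target cup-to-disc ratios are exact up to
#' rasterization. Brightness ordering `cup > disc > background` mirrors real
#' optic-nerve-head photographs. Defaults describe a realistic mid-size disc
#' and moderate cupping on the 512 canvas.
#'
#' @param size `c(height, width)` in pixels.
#' @param disc_center `(row, col)`; default slightly temporal of the canvas
#'   centre.
#' @param disc_axes `(semi-axis vertical, semi-axis horizontal)` pixels.
#' @param cdr_h,cdr_v target cup-to-disc ratios in (0, 1).
#' @param disc_brightness,cup_brightness,background_level gray levels 0-255.
#' @param n_vessels number of vessel random walks seeded at the disc centre.
#' @param vessel_width vessel stamp diameter in pixels.
#' @param noise_sigma Gaussian pixel noise SD in gray levels.
#' @param blur_sigma Gaussian blur SD in pixels.
#' @param seed integer RNG seed; same spec and seed give bit-identical output.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = phantom_profile("small"),
                         disc_center = NULL,
                         disc_axes = c(48, 52),
                         cdr_h = 0.55, cdr_v = 0.55,
                         disc_brightness = 150,
                         cup_brightness = 225,
                         background_level = 70,
                         n_vessels = 6,
                         vessel_width = 5,
                         noise_sigma = 8,
                         blur_sigma = 1.5,
                         seed = 1L) {
  size <- as.integer(size)
  if (is.null(disc_center)) disc_center <- c(size[1] / 2, size[2] * 0.55)
  if (cdr_h <= 0 || cdr_h >= 1 || cdr_v <= 0 || cdr_v >= 1)
    stopf("cup must lie strictly inside the disc: cdr_h, cdr_v in (0, 1)")
  if (!(cup_brightness > disc_brightness && disc_brightness > background_level))
    stopf("brightness ordering must be cup > disc > background")
  structure(list(size = size, disc_center = as.numeric(disc_center),
                 disc_axes = as.numeric(disc_axes), cdr_h = cdr_h, cdr_v = cdr_v,
                 disc_brightness = disc_brightness,
                 cup_brightness = cup_brightness,
                 background_level = background_level,
                 n_vessels = as.integer(n_vessels),
                 vessel_width = vessel_width,
                 noise_sigma = noise_sigma, blur_sigma = blur_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Filled ellipse mask, 0-based centre coordinates, semi-axes (vertical, horizontal).
ellipse_mask <- function(height, width, center, axes) {
  r <- matrix(0:(height - 1), height, width)
  c_ <- matrix(0:(width - 1), height, width, byrow = TRUE)
  ((r - center[1]) / axes[1])^2 + ((c_ - center[2]) / axes[2])^2 <= 1
}

# Stamp random-walk vessels radiating from the disc centre; smooth heading
# changes make dark curvilinear occluders whose exact shape is irrelevant.
vessel_walks <- function(height, width, center, n_vessels, vessel_width) {
  mask <- matrix(FALSE, height, width)
  if (n_vessels == 0L) return(mask)
  rad <- max(1L, floor(vessel_width / 2))
  offs <- which(ellipse_mask(2L * rad + 1L, 2L * rad + 1L,
                             c(rad, rad), c(rad, rad) + 0.1), arr.ind = TRUE)
  offs <- offs - rad - 1L  # offsets around the stamp centre
  headings <- stats::runif(n_vessels, 0, 2 * pi)
  n_steps <- ceiling(1.5 * max(height, width))
  for (v in seq_len(n_vessels)) {
    pos <- center
    h <- headings[v]
    for (s in seq_len(n_steps)) {
      h <- h + stats::rnorm(1, 0, 0.12)
      pos <- pos + c(sin(h), cos(h))
      pr <- round(pos[1]); pc <- round(pos[2])
      if (pr < 0 || pc < 0 || pr >= height || pc >= width) break
      rr <- offs[, 1] + pr + 1L; cc <- offs[, 2] + pc + 1L
      ok <- rr >= 1L & rr <= height & cc >= 1L & cc <= width
      mask[cbind(rr[ok], cc[ok])] <- TRUE
    }
  }
  mask
}

#' Generate a fundus phantom with ground truth
#'
#' The scene is built at the stated brightness levels with a radial vignette,
#' vessels overwrite disc/cup intensities at `background_level - 40`, then the
#' image is Gaussian-blurred and Gaussian noise is added, clipped to 0-255.
#' Ground-truth region parameters are computed from the noiseless masks.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (a [fundus_image()]), logical masks `disc`,
#'   `cup`, `vessels`, and `truth` (a [region_params()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$size[1]; w <- spec$size[2]
  disc <- ellipse_mask(h, w, spec$disc_center, spec$disc_axes)
  cup <- ellipse_mask(h, w, spec$disc_center,
                      c(spec$cdr_v * spec$disc_axes[1],
                        spec$cdr_h * spec$disc_axes[2]))
  withr::with_seed(spec$seed, {
    vessels <- vessel_walks(h, w, spec$disc_center, spec$n_vessels,
                            spec$vessel_width)
    r <- matrix(0:(h - 1), h, w); c_ <- matrix(0:(w - 1), h, w, byrow = TRUE)
    dcent <- sqrt((r - (h - 1) / 2)^2 + (c_ - (w - 1) / 2)^2)
    vig <- 1 - 0.25 * (dcent / max(dcent))^2
    scene <- spec$background_level * vig
    scene[disc] <- spec$disc_brightness
    scene[cup] <- spec$cup_brightness
    scene[vessels] <- spec$background_level - 40
    gains <- c(1.15, 1, 0.55)  # crude red-dominant colour cast
    px <- array(0, c(h, w, 3))
    for (ch in 1:3) {
      plane <- scene * gains[ch]
      if (spec$blur_sigma > 0)
        plane <- EBImage::gblur(plane, sigma = spec$blur_sigma)
      if (spec$noise_sigma > 0)
        plane <- plane + stats::rnorm(h * w, 0, spec$noise_sigma)
      px[, , ch] <- clamp(round(plane), 0, 255)
    }
  })
  list(image = fundus_image(px),
       disc = disc, cup = cup, vessels = vessels,
       truth = region_params_from_masks(disc, cup))
}

#' Specify a grader-marking simulation
#'
#' Areas get multiplicative log-normal jitter (keeping them positive and
#' scale-proportional, as inter-grader spread grows with image size);
#' centroids and CDRs get additive Gaussian jitter. With probability
#' `outlier_rate` per (image, grader, parameter) the record becomes a gross
#' error: its perturbation is inflated by `outlier_scale` with magnitude
#' bounded away from zero (at least one base-jitter SD before scaling, the
#' way a real mis-marking is displaced rather than merely noisier), and it is
#' tagged in a ground-truth outlier ledger.
#'
#' @param n_graders number of simulated manual graders.
#' @param area_jitter_cv coefficient of variation of the area jitter.
#' @param centroid_jitter_sd per-coordinate centroid jitter SD in pixels.
#' @param cdr_jitter_sd CDR jitter SD in ratio units.
#' @param outlier_rate probability in \[0, 1\] per (image, grader, parameter).
#' @param outlier_scale jitter multiplier for outliers (> 1).
#' @param seed integer RNG seed.
#' @return object of class `grader_sim_spec`.
#' @export
grader_sim_spec <- function(n_graders = 6, area_jitter_cv = 0.05,
                            centroid_jitter_sd = 2, cdr_jitter_sd = 0.03,
                            outlier_rate = 0, outlier_scale = 5, seed = 1L) {
  if (outlier_rate < 0 || outlier_rate > 1) stopf("outlier_rate must be in [0, 1]")
  if (outlier_scale <= 1) stopf("outlier_scale must be > 1")
  structure(list(n_graders = as.integer(n_graders),
                 area_jitter_cv = area_jitter_cv,
                 centroid_jitter_sd = centroid_jitter_sd,
                 cdr_jitter_sd = cdr_jitter_sd,
                 outlier_rate = outlier_rate, outlier_scale = outlier_scale,
                 seed = as.integer(seed)),
            class = "grader_sim_spec")
}

param_groups <- c("disc_area", "disc_centroid", "cup_area", "cup_centroid",
                  "hcdr", "vcdr")

#' Simulate a multi-grader marking table from ground truth
#'
#' @param truth data.frame with columns `image_id` plus the eight region
#'   parameter columns (as produced by [run_simulate()] or assembled from
#'   [region_params_from_masks()] results).
#' @param spec a [grader_sim_spec()].
#' @return list with `markings` (marking table data.frame, graders
#'   `"1"..."n"`) and `outliers` (ledger data.frame `image_id, grader_id,
#'   param` of injected outliers).
#' @export
simulate_markings <- function(truth, spec) {
  stopifnot(inherits(spec, "grader_sim_spec"))
  if (nrow(truth) == 0L) stopf("truth table is empty")
  truth$image_id <- as.character(truth$image_id)
  rows <- vector("list", nrow(truth) * spec$n_graders)
  led <- list()
  k <- 0L
  # standardized perturbation: plain N(0,1) for regular jitter; for gross
  # errors a random sign with magnitude 1 + |N(0,1)|, inflated by the scale
  zdraw <- function(outlier, scale) {
    if (!outlier) return(stats::rnorm(1))
    sample(c(-1, 1), 1) * (1 + abs(stats::rnorm(1))) * scale
  }
  withr::with_seed(spec$seed, {
    for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      for (g in seq_len(spec$n_graders)) {
        out <- stats::runif(6) < spec$outlier_rate
        names(out) <- param_groups
        z <- function(p) zdraw(out[[p]], spec$outlier_scale)
        k <- k + 1L
        rows[[k]] <- data.frame(
          image_id = tr$image_id, grader_id = as.character(g),
          disc_area = tr$disc_area * exp(spec$area_jitter_cv * z("disc_area")),
          disc_centroid_row = tr$disc_centroid_row +
            spec$centroid_jitter_sd * z("disc_centroid"),
          disc_centroid_col = tr$disc_centroid_col +
            spec$centroid_jitter_sd * z("disc_centroid"),
          cup_area = tr$cup_area * exp(spec$area_jitter_cv * z("cup_area")),
          cup_centroid_row = tr$cup_centroid_row +
            spec$centroid_jitter_sd * z("cup_centroid"),
          cup_centroid_col = tr$cup_centroid_col +
            spec$centroid_jitter_sd * z("cup_centroid"),
          hcdr = max(0.01, tr$hcdr + spec$cdr_jitter_sd * z("hcdr")),
          vcdr = max(0.01, tr$vcdr + spec$cdr_jitter_sd * z("vcdr")),
          stringsAsFactors = FALSE)
        if (any(out))
          led[[length(led) + 1L]] <- data.frame(
            image_id = tr$image_id, grader_id = as.character(g),
            param = param_groups[out], stringsAsFactors = FALSE)
      }
    }
  })
  ledger <- if (length(led)) do.call(rbind, led) else
    data.frame(image_id = character(), grader_id = character(),
               param = character(), stringsAsFactors = FALSE)
  list(markings = validate_markings(do.call(rbind, rows)), outliers = ledger)
}

# Flatten a region_params into the marking-table row layout.
params_row <- function(image_id, grader_id, rp) {
  data.frame(image_id = image_id, grader_id = grader_id,
             disc_area = rp$disc_area,
             disc_centroid_row = rp$disc_centroid[1],
             disc_centroid_col = rp$disc_centroid[2],
             cup_area = rp$cup_area,
             cup_centroid_row = rp$cup_centroid[1],
             cup_centroid_col = rp$cup_centroid[2],
             hcdr = rp$hcdr, vcdr = rp$vcdr, stringsAsFactors = FALSE)
}
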