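#' @title Optic cup segmentation: four-loop thresholding cascade
#' @description The cup is the brightest region inside the disc ROI. A
#'   cascade of four multilevel-thresholding loops (k = 3, 2, 4, 3; image
#'   enhancement on in the first two loops, off in the last two) segments
#'   candidate cups; each candidate is cleaned (small-spot removal, vessel
#'   gap filling, morphological closing), approximated by a circular Hough
#'   fit, and accepted only if its area exceeds the minimum-cup floor and the
#'   fitted cup does not touch the disc boundary. The first passing loop
#'   wins; if all four fail the image carries no automatic cup.
#' @name cup-segment
NULL

#' The four cascade loop configurations
#'
#' @return data.frame with columns `loop` (1..4), `k` (3, 2, 4, 3) and
#'   `enhance` (TRUE, TRUE, FALSE, FALSE).
#' @export
cup_loop_configs <- function() {
  data.frame(loop = 1:4, k = c(3L, 2L, 4L, 3L),
             enhance = c(TRUE, TRUE, FALSE, FALSE))
}

#' Cup cascade configuration
#'
#' @param min_spot bright components smaller than this many pixels are
#'   discarded before choosing the cup candidate.
#' @param closing_radius disk radius of the morphological closing that seals
#'   gaps left by removed vessels.
#' @param area_floor minimum acceptable cup area in pixels, stated for the
#'   `area_floor_frame_width`-wide frame in which it was calibrated.
#' @param area_floor_frame_width reference frame width for the floor.
#' @param scale_area_floor scale the floor by `(width / frame_width)^2`; when
#'   `FALSE` the literal constant is used at any resolution.
#' @param hough_range cup radius search range as fractions of the disc
#'   equivalent radius.
#' @param enhance_quantiles percentile pair for the linear contrast stretch
#'   used as "image enhancement" in loops 1-2.
#' @param fou_width footprint-of-uncertainty width for thresholding.
#' @param area_test_after_hough apply the area floor to the Hough-fitted cup
#'   (default) rather than the pre-fit candidate.
#' @param seed master seed for the per-loop threshold searches.
#' @return list of class `cup_config`.
#' @export
cup_config <- function(min_spot = 50, closing_radius = 5, area_floor = 3000,
                       area_floor_frame_width = 2376, scale_area_floor = TRUE,
                       hough_range = c(0.15, 0.6),
                       enhance_quantiles = c(0.01, 0.99), fou_width = 10,
                       area_test_after_hough = TRUE, seed = 202L) {
  structure(list(min_spot = min_spot, closing_radius = closing_radius,
                 area_floor = area_floor,
                 area_floor_frame_width = area_floor_frame_width,
                 scale_area_floor = scale_area_floor,
                 hough_range = hough_range,
                 enhance_quantiles = enhance_quantiles,
                 fou_width = fou_width,
                 area_test_after_hough = area_test_after_hough,
                 seed = as.integer(seed)),
            class = "cup_config")
}

#' Brightest surviving region of a label image
#'
#' Takes the top label class, removes connected components smaller than
#' `min_spot` pixels (strictly smaller: a 50-pixel spot survives the default
#' floor of 50), and keeps the largest survivor, breaking ties by distance to
#' the window centre.
#'
#' @param labels integer label matrix from [apply_thresholds()].
#' @param min_spot minimum component size in pixels.
#' @param center optional `(row, col)` tie-break centre; defaults to the
#'   window centre.
#' @return logical mask (empty when no component survives).
#' @export
brightest_region <- function(labels, min_spot = 50, center = NULL) {
  k <- attr(labels, "k") %||% max(labels)
  mask <- labels == k
  if (!any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(sizes >= min_spot)
  if (!length(keep)) return(mask & FALSE)
  mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  if (is.null(center)) center <- c((nrow(mask) - 1) / 2, (ncol(mask) - 1) / 2)
  largest_component(mask, tie_center = center)
}

#' Refine a cup candidate with vessels and closing
#'
#' Vessel pixels whose components touch the candidate (8-connectivity
#' through the union) are added back to fill the gaps the removed vessels
#' left in the bright spot; a morphological closing then seals remaining
#' small gaps, holes are filled, and the largest connected component is
#' returned.
#'
#' @param mask logical cup candidate.
#' @param vessels logical vessel mask in the same frame.
#' @param closing_radius disk radius for the closing (0 skips it).
#' @return logical mask; empty input gives empty output.
#' @export
refine_cup <- function(mask, vessels, closing_radius = 5) {
  stopifnot(identical(dim(mask), dim(vessels)))
  if (!any(mask)) return(mask)
  u <- mask | vessels
  lab <- label_components(u)
  touching <- unique(lab[mask & lab > 0L])
  out <- matrix(lab %in% touching, nrow(mask), ncol(mask))
  if (closing_radius > 0)
    out <- EBImage::closing(out * 1, disk_brush(closing_radius)) > 0.5
  out <- EBImage::fillHull(out * 1) > 0.5
  largest_component(matrix(out, nrow(mask), ncol(mask)))
}

#' Fit a circle to a mask boundary with the Hough transform
#'
#' Votes from the mask's boundary pixels over the radius sweep
#' `[r_min, r_max]`; the accumulator is lightly smoothed (3x3) and votes are
#' normalized by the expected hits per boundary pixel so radii compete
#' fairly. Robust to missing arcs (e.g. half-moon shapes) and boundary
#' jitter.
#'
#' @param mask non-empty logical mask.
#' @param r_min,r_max radius sweep bounds in pixels.
#' @param center_mask optional logical mask restricting admissible circle
#'   centres (e.g. the disc interior when fitting cups).
#' @return list with `center` (0-based `(row, col)`), `radius` and the
#'   normalized vote `score`.
#' @export
hough_circle_fit <- function(mask, r_min, r_max, center_mask = NULL) {
  if (!any(mask)) stopf("cannot fit a circle to an empty mask")
  boundary <- mask & !erode8(mask)
  bp <- which(boundary, arr.ind = TRUE)
  if (nrow(bp) == 0L) stopf("mask has no boundary pixels")
  h <- nrow(mask); w <- ncol(mask)
  radii <- seq(max(2L, as.integer(floor(r_min))), max(2L, as.integer(ceiling(r_max))))
  smooth_k <- matrix(1 / 9, 3, 3)
  best <- list(score = -Inf)
  for (r in radii) {
    n_ang <- max(32L, min(360L, as.integer(round(2 * pi * r * 2))))
    theta <- seq(0, 2 * pi, length.out = n_ang + 1L)[-(n_ang + 1L)]
    acc <- matrix(0, h, w)
    cr <- round(rep(bp[, 1], each = n_ang) + r * sin(theta))
    cc <- round(rep(bp[, 2], each = n_ang) + r * cos(theta))
    ok <- cr >= 1 & cr <= h & cc >= 1 & cc <= w
    idx <- cr[ok] + (cc[ok] - 1L) * h
    votes <- tabulate(idx, nbins = h * w)
    acc[] <- votes
    acc <- EBImage::filter2(acc, smooth_k, boundary = "replicate")
    if (!is.null(center_mask)) acc[!center_mask] <- 0
    # expected hits per pixel voting on a cell is ~ n_ang / (2 pi r)
    score <- max(acc) / (n_ang / (2 * pi * r))
    if (score > best$score) {
      m <- which.max(acc)
      best <- list(center = c((m - 1) %% h, (m - 1) %/% h), radius = r,
                   score = score)
    }
  }
  best
}

# Linear contrast stretch of a gray ROI to full range between the given
# percentiles ("image enhancement" of cascade loops 1-2).
contrast_stretch <- function(gray, quantiles = c(0.01, 0.99)) {
  q <- stats::quantile(gray, quantiles, names = FALSE)
  if (q[2] <= q[1]) return(gray)
  clamp((gray - q[1]) / (q[2] - q[1]) * 255, 0, 255)
}

# 8-adjacency contact between a cup mask and the outside of the disc.
touches_disc_boundary <- function(cup, disc) {
  any(dilate8(cup) & !disc)
}

#' Segment the optic cup inside the disc ROI
#'
#' Runs the four-loop cascade in order, never revisiting a loop. Each loop
#' (optionally) enhances the ROI, multilevel-thresholds it with the loop's k,
#' extracts and refines the brightest region, fits the Hough circle, and
#' accepts the fitted cup only if its area exceeds the (optionally
#' resolution-scaled) floor and it does not touch the disc boundary.
#'
#' @param roi_gray numeric ROI matrix (0-255), typically the inpainted green
#'   channel restricted to the disc ROI.
#' @param disc logical disc mask in the ROI frame.
#' @param vessels logical vessel mask in the ROI frame.
#' @param config a [cup_config()].
#' @param image_width full-image width in pixels, used to scale the area
#'   floor across resolutions.
#' @return object of class `cup_result`: `success`, `loop_used`, `mask`
#'   (ROI frame), `area`, `centroid` (ROI frame, 0-based), `circle`
#'   (`(row, col, radius)`), and a per-loop `log` data.frame recording every
#'   cascade decision (`loop`, `k`, `enhance`, `area`, `touches`,
#'   `accepted`).
#' @export
segment_cup <- function(roi_gray, disc, vessels, config = cup_config(),
                        image_width = ncol(roi_gray)) {
  stopifnot(identical(dim(roi_gray), dim(disc)),
            identical(dim(roi_gray), dim(vessels)))
  if (!any(disc)) stopf("disc mask is empty; cup segmentation needs a disc")
  floor_px <- if (config$scale_area_floor) {
    config$area_floor * (image_width / config$area_floor_frame_width)^2
  } else config$area_floor
  disc_r <- sqrt(sum(disc) / pi)
  # admissible cup centres: well inside the disc
  center_ok <- EBImage::erode(disc * 1, disk_brush(4)) > 0.5
  if (!any(center_ok)) center_ok <- disc
  loops <- cup_loop_configs()
  log_rows <- list()
  result <- structure(list(success = FALSE, loop_used = NA_integer_,
                           mask = disc & FALSE, area = 0,
                           centroid = c(NA_real_, NA_real_), circle = NULL,
                           log = NULL),
                      class = "cup_result")
  for (i in seq_len(nrow(loops))) {
    lp <- loops[i, ]
    img <- if (lp$enhance) contrast_stretch(roi_gray, config$enhance_quantiles)
           else roi_gray
    hist <- gray_histogram(img)
    area <- 0; touches <- NA; circ <- NULL; fitted <- NULL
    if (sum(hist > 0) >= lp$k + 1) {
      ts <- de_optimize(hist, lp$k,
                        de_params(seed = sub_seed(config$seed, lp$loop)),
                        config$fou_width)
      cand <- brightest_region(apply_thresholds(img, ts), config$min_spot)
      # only vessels near the candidate and inside the disc may bridge gaps;
      # whole vessel branches would add long thin arms to the cup
      if (any(cand)) {
        near <- EBImage::dilate(cand * 1,
                                disk_brush(2 * config$closing_radius)) > 0.5
        cand <- refine_cup(cand, vessels & near & disc, config$closing_radius)
      }
      if (any(cand)) {
        # clip to the disc and shave residual thin protrusions
        cand <- cand & disc
        if (config$closing_radius > 0)
          cand <- EBImage::opening(cand * 1,
                                   disk_brush(config$closing_radius)) > 0.5
        cand <- largest_component(matrix(cand, nrow(roi_gray)))
      }
      if (any(cand)) {
        pre_area <- sum(cand)
        circ <- hough_circle_fit(cand, config$hough_range[1] * disc_r,
                                 config$hough_range[2] * disc_r,
                                 center_mask = center_ok)
        fitted <- circle_mask(nrow(roi_gray), ncol(roi_gray),
                              circ$center, circ$radius)
        area <- if (config$area_test_after_hough) sum(fitted) else pre_area
        touches <- touches_disc_boundary(fitted, disc)
      }
    }
    accepted <- !is.null(fitted) && area > floor_px && !isTRUE(touches)
    log_rows[[i]] <- data.frame(loop = lp$loop, k = lp$k, enhance = lp$enhance,
                                area = area, touches = isTRUE(touches),
                                accepted = accepted)
    if (accepted) {
      result$success <- TRUE
      result$loop_used <- lp$loop
      result$mask <- fitted
      result$area <- sum(fitted)
      result$centroid <- mask_centroid(fitted)
      result$circle <- c(circ$center, circ$radius)
      break
    }
  }
  result$log <- do.call(rbind, log_rows)
  result
}
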