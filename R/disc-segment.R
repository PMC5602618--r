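#' @title Optic disc localization and level-set segmentation
#' @description The optic nerve head is localized as the largest connected
#'   component of the brightest multilevel-threshold class of the inpainted
#'   green channel; the disc boundary is then segmented inside a square ROI
#'   with an edge-based level-set active contour (distance-regularized
#'   geodesic evolution). High-quality images take a single level-set pass;
#'   low-quality images re-localize on the first contour, split the refined
#'   window into left/right halves and evolve a second level set in each.
#' @name disc-segment
NULL

#' Level-set evolution parameters
#'
#' @param dt time step (> 0).
#' @param iterations iteration cap (0 returns the initialization unchanged).
#' @param mu distance-regularization weight (stability requires `mu * dt < 0.25`).
#' @param lambda edge (geodesic curvature) weight.
#' @param alpha balloon/area weight; negative values expand the contour.
#' @param sigma Gaussian smoothing SD (pixels) for the edge indicator.
#' @param tol convergence tolerance: fraction of pixels changing sign
#'   between checks below which evolution stops.
#' @return object of class `level_set_params`.
#' @export
level_set_params <- function(dt = 1, iterations = 400, mu = 0.2, lambda = 5,
                             alpha = -1.8, sigma = 2, tol = 1e-3) {
  if (iterations < 0) stopf("iterations must be >= 0")
  if (dt <= 0) stopf("time step must be positive")
  structure(list(dt = dt, iterations = as.integer(iterations), mu = mu,
                 lambda = lambda, alpha = alpha, sigma = sigma, tol = tol),
            class = "level_set_params")
}

# Central differences with replicated borders.
grad_central <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gr <- (m[c(2:nr, nr), ] - m[c(1, 1:(nr - 1)), ]) / 2
  gc <- (m[, c(2:nc, nc)] - m[, c(1, 1:(nc - 1))]) / 2
  list(r = gr, c = gc)
}

laplacian4 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c(2:nr, nr), ] + m[c(1, 1:(nr - 1)), ] +
    m[, c(2:nc, nc)] + m[, c(1, 1:(nc - 1))] - 4 * m
}

#' Evolve a level-set active contour
#'
#' Edge-based evolution on the signed function phi (negative inside):
#' `phi_t = mu R(phi) + lambda delta(phi) div(g grad(phi)/|grad(phi)|) +
#' alpha g delta(phi)` with edge indicator
#' `g = 1 / (1 + |grad(G_sigma * I)|^2)`, distance regularization `R`, and a
#' smoothed Dirac `delta`. Evolution stops at the iteration cap or when the
#' fraction of sign changes between checks falls below the tolerance.
#'
#' @param gray numeric ROI matrix (0-255).
#' @param init non-empty logical initialization mask inside the ROI.
#' @param params a [level_set_params()].
#' @return logical mask of the final interior; an empty result carries
#'   attribute `failed = TRUE`.
#' @export
level_set_evolve <- function(gray, init, params = level_set_params()) {
  stopifnot(identical(dim(gray), dim(init)))
  if (params$iterations == 0L) return(init)
  if (!any(init)) stopf("initialization mask is empty")
  sm <- if (params$sigma > 0) EBImage::gblur(gray, sigma = params$sigma) else gray
  gI <- grad_central(sm)
  g <- 1 / (1 + gI$r^2 + gI$c^2)
  vg <- grad_central(g)
  c0 <- 2
  phi <- ifelse(init, -c0, c0)
  eps <- 1.5
  check_every <- 10L
  prev_sign <- phi < 0
  for (it in seq_len(params$iterations)) {
    gp <- grad_central(phi)
    s <- sqrt(gp$r^2 + gp$c^2) + 1e-10
    nr_ <- gp$r / s; nc_ <- gp$c / s
    dn <- grad_central(nr_)$r + grad_central(nc_)$c  # curvature
    dist_reg <- laplacian4(phi) - dn
    dirac <- ifelse(abs(phi) <= eps, (1 + cos(pi * phi / eps)) / (2 * eps), 0)
    edge_term <- dirac * (vg$r * nr_ + vg$c * nc_ + g * dn)
    area_term <- dirac * g
    phi <- phi + params$dt * (params$mu * dist_reg +
                                params$lambda * edge_term +
                                params$alpha * area_term)
    if (it %% check_every == 0L) {
      cur <- phi < 0
      frac <- mean(cur != prev_sign)
      prev_sign <- cur
      if (frac < params$tol) break
    }
  }
  out <- phi < 0
  if (!any(out)) attr(out, "failed") <- TRUE
  out
}

#' Localize the optic nerve head
#'
#' Multilevel-thresholds the (vessel-inpainted) green channel, takes the
#' largest connected component of the brightest class, and centres a square
#' ROI of side `roi_fraction * width` on its centroid, clipped to the image.
#' Localization fails (a return state, not an error) when the brightest
#' component is smaller than `min_component` of the image area.
#'
#' @param green numeric matrix: the inpainted green channel (0-255).
#' @param k number of thresholds for the localization split.
#' @param de a [de_params()] for the threshold search.
#' @param roi_fraction ROI side as a fraction of image width.
#' @param min_component minimum component size as a fraction of image area.
#' @param fou_width footprint-of-uncertainty width.
#' @return list `(localized, roi)`; `roi` is `NULL` when not localized.
#' @export
localize_disc <- function(green, k = 2, de = de_params(seed = 101L),
                          roi_fraction = 0.25, min_component = 5e-4,
                          fou_width = 10) {
  h <- nrow(green); w <- ncol(green)
  hist <- gray_histogram(green)
  if (sum(hist > 0) < k + 1)
    return(list(localized = FALSE, roi = NULL))
  ts <- de_optimize(hist, k, de, fou_width)
  lab <- apply_thresholds(green, ts)
  bright <- lab == attr(lab, "k")
  if (!any(bright)) return(list(localized = FALSE, roi = NULL))
  comp <- largest_component(bright)
  if (sum(comp) < min_component * h * w)
    return(list(localized = FALSE, roi = NULL))
  ctr <- mask_centroid(comp)
  side <- min(as.integer(round(roi_fraction * w)), h, w)
  row0 <- clamp(as.integer(round(ctr[1] - side / 2)), 0L, h - side)
  col0 <- clamp(as.integer(round(ctr[2] - side / 2)), 0L, w - side)
  list(localized = TRUE, roi = roi_window(row0, col0, side, side))
}

#' Disc segmentation configuration
#'
#' Bundles the knobs of the localization + level-set stage. The
#' initialization is a circle inscribed at `init_fraction` of the ROI
#' half-side; the double path re-centres the ROI on the first contour before
#' the split refinement.
#'
#' @param vessel a [vessel_params()] or `NULL` for defaults.
#' @param ls a [level_set_params()].
#' @param k_localize thresholds used for localization.
#' @param roi_fraction,min_component see [localize_disc()].
#' @param init_fraction initial circle radius as a fraction of ROI half-side.
#' @param fou_width footprint-of-uncertainty width.
#' @param seed master seed for the stage's threshold searches.
#' @return list of class `disc_config`.
#' @export
disc_config <- function(vessel = NULL, ls = level_set_params(),
                        k_localize = 2, roi_fraction = 0.25,
                        min_component = 5e-4, init_fraction = 0.7,
                        fou_width = 10, seed = 101L) {
  structure(list(vessel = vessel, ls = ls, k_localize = k_localize,
                 roi_fraction = roi_fraction, min_component = min_component,
                 init_fraction = init_fraction, fou_width = fou_width,
                 seed = as.integer(seed)),
            class = "disc_config")
}

circle_mask <- function(height, width, center, radius) {
  ellipse_mask(height, width, center, c(radius, radius))
}

#' Segment the optic disc
#'
#' Full disc stage: vessel extraction, green-channel inpainting,
#' localization, then level-set segmentation. High-quality images take a
#' single evolution initialized from an inscribed circle; low-quality images
#' re-centre the window on the first contour (second localization), split it
#' vertically into left and right halves, evolve a level set in each half
#' initialized from the first contour's restriction, and keep the largest
#' connected component of the union.
#'
#' @param image a [fundus_image()]; its `profile` selects the path.
#' @param config a [disc_config()].
#' @param vessels optional precomputed vessel mask (else extracted here).
#' @param inpainted_green optional precomputed inpainted green channel.
#' @return object of class `disc_result`: `localized`, `roi`, `mask`
#'   (full-image frame), `area`, `centroid`, `path_used`, plus the
#'   `inpainted_green` and `vessels` intermediates for downstream stages.
#' @export
segment_disc <- function(image, config = disc_config(), vessels = NULL,
                         inpainted_green = NULL) {
  stopifnot(inherits(image, "fundus_image"))
  if (is.null(vessels)) vessels <- extract_vessels(image, config$vessel)
  if (is.null(inpainted_green)) {
    iters <- (config$vessel %||% vessel_params())$iterations
    inpainted_green <- inpaint_channel(green_channel(image), vessels,
                                       iterations = iters)
  }
  loc <- localize_disc(inpainted_green, k = config$k_localize,
                       de = de_params(seed = sub_seed(config$seed, 1)),
                       roi_fraction = config$roi_fraction,
                       min_component = config$min_component,
                       fou_width = config$fou_width)
  fail <- structure(list(localized = FALSE, roi = NULL, mask = NULL,
                         area = 0, centroid = c(NA_real_, NA_real_),
                         path_used = NA_character_,
                         inpainted_green = inpainted_green, vessels = vessels),
                    class = "disc_result")
  if (!loc$localized) return(fail)
  roi <- loc$roi
  roi_img <- roi_crop(inpainted_green, roi)
  half <- roi$n_rows / 2
  init <- circle_mask(roi$n_rows, roi$n_cols,
                      c((roi$n_rows - 1) / 2, (roi$n_cols - 1) / 2),
                      config$init_fraction * half)
  first <- level_set_evolve(roi_img, init, config$ls)
  if (!any(first)) return(fail)
  if (image$profile == "high_quality") {
    mask_roi <- largest_component(first)
    path <- "single"
  } else {
    # second localization: re-centre the window on the first contour
    ctr <- mask_centroid(first)
    side <- roi$n_rows
    row0 <- clamp(as.integer(round(roi$row0 + ctr[1] - side / 2)),
                  0L, image$height - side)
    col0 <- clamp(as.integer(round(roi$col0 + ctr[2] - side / 2)),
                  0L, image$width - side)
    roi2 <- roi_window(row0, col0, side, side)
    first_full <- roi_uncrop(first, roi, image$height, image$width)
    img2 <- roi_crop(inpainted_green, roi2)
    init2 <- roi_crop(first_full, roi2)
    halves <- list(1:floor(side / 2), (floor(side / 2) + 1):side)
    merged <- matrix(FALSE, side, side)
    for (hcols in halves) {
      sub_init <- init2[, hcols, drop = FALSE]
      if (!any(sub_init)) next
      sub <- level_set_evolve(img2[, hcols, drop = FALSE], sub_init, config$ls)
      merged[, hcols] <- merged[, hcols] | sub
    }
    if (!any(merged)) return(fail)
    mask_roi <- largest_component(merged)
    roi <- roi2
    path <- "double"
  }
  mask <- roi_uncrop(mask_roi, roi, image$height, image$width)
  structure(list(localized = TRUE, roi = roi, mask = mask,
                 area = sum(mask), centroid = mask_centroid(mask),
                 path_used = path,
                 inpainted_green = inpainted_green, vessels = vessels),
            class = "disc_result")
}
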