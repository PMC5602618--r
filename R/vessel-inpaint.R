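#' @title Vessel extraction and diffusion inpainting
#' @description Blood vessels are thin dark curvilinear structures that
#'   distort both the level-set edge map and the thresholding histogram.
#'   They are extracted with a morphological black top-hat on the green
#'   channel and erased by iterated diffusion inpainting before segmentation.
#' @name vessel-inpaint
NULL

#' Vessel extraction parameters
#'
#' @param radius structuring-element radius in pixels; default scales with
#'   image width (7 px at width 512) because apparent vessel calibre scales
#'   with resolution. Resolved when `NULL` at extraction time.
#' @param threshold_rule `"otsu"` (default) or `"fixed"` on the top-hat
#'   response.
#' @param fixed_threshold gray levels, used when `threshold_rule = "fixed"`.
#' @param presmooth_sigma Gaussian denoising SD (pixels) applied before the
#'   top-hat so pixel noise does not masquerade as vessel response.
#' @param iterations inpainting iteration cap.
#' @return object of class `vessel_params`.
#' @export
vessel_params <- function(radius = NULL, threshold_rule = c("otsu", "fixed"),
                          fixed_threshold = 10, presmooth_sigma = 1.5,
                          iterations = 100) {
  threshold_rule <- match.arg(threshold_rule)
  if (!is.null(radius) && radius < 1) stopf("radius must be >= 1")
  if (iterations < 1) stopf("iterations must be >= 1")
  structure(list(radius = radius, threshold_rule = threshold_rule,
                 fixed_threshold = fixed_threshold,
                 presmooth_sigma = presmooth_sigma, iterations = iterations),
            class = "vessel_params")
}

default_vessel_radius <- function(width) max(3L, as.integer(round(7 * width / 512)))

#' Extract the blood-vessel mask
#'
#' Black top-hat (morphological closing minus image) of the denoised green
#' channel with a disk structuring element. The black polarity is used
#' because vessels are darker than the surrounding retina. The response is
#' normalized by the local closing (relative darkness) so that vessels
#' crossing the bright disc and vessels on the dimmer periphery score
#' comparably, then thresholded by Otsu's rule (or a fixed level).
#'
#' @param image a [fundus_image()].
#' @param params a [vessel_params()]; `NULL` for defaults.
#' @return logical mask, true on vessel pixels.
#' @export
extract_vessels <- function(image, params = NULL) {
  stopifnot(inherits(image, "fundus_image"))
  params <- params %||% vessel_params()
  radius <- params$radius %||% default_vessel_radius(image$width)
  if (radius > min(image$height, image$width) / 2)
    stopf("structuring-element radius %d exceeds half the image size", radius)
  g <- green_channel(image) / 255
  if (params$presmooth_sigma > 0)
    g <- EBImage::gblur(g, sigma = params$presmooth_sigma)
  cl <- EBImage::closing(g, disk_brush(radius))
  rel <- (cl - g) / pmax(cl, 0.05)
  thr <- if (params$threshold_rule == "otsu") {
    if (max(rel) <= min(rel)) Inf  # constant response: no vessels
    else EBImage::otsu(EBImage::Image(rel), range = range(rel))
  } else {
    params$fixed_threshold / 255
  }
  matrix(rel > thr, nrow(rel), ncol(rel))
}

# Oliveira-style normalized 3x3 diffusion kernel: zero centre, cross 0.1875,
# diagonals 0.0625 (weights sum to 1).
diffusion_kernel <- function() {
  matrix(c(0.0625, 0.1875, 0.0625,
           0.1875, 0,      0.1875,
           0.0625, 0.1875, 0.0625), 3, 3)
}

# Diffuse one channel: masked pixels repeatedly replaced by the kernel
# average of their neighbourhood; unmasked pixels reset after every pass
# (equivalently, only masked pixels are ever updated). Neighbour indices are
# precomputed with replicated borders so each pass touches masked pixels only.
inpaint_channel <- function(mat, mask, iterations = 100, tol = 0.1) {
  idx <- which(mask)
  if (!length(idx)) return(mat)
  h <- nrow(mat); w <- ncol(mat)
  r <- (idx - 1L) %% h + 1L
  c_ <- (idx - 1L) %/% h + 1L
  nb <- function(dr, dc) clamp(r + dr, 1L, h) + (clamp(c_ + dc, 1L, w) - 1L) * h
  cross <- cbind(nb(-1L, 0L), nb(1L, 0L), nb(0L, -1L), nb(0L, 1L))
  diag_ <- cbind(nb(-1L, -1L), nb(-1L, 1L), nb(1L, -1L), nb(1L, 1L))
  x <- mat
  for (it in seq_len(iterations)) {
    new <- 0.1875 * (x[cross[, 1]] + x[cross[, 2]] + x[cross[, 3]] + x[cross[, 4]]) +
      0.0625 * (x[diag_[, 1]] + x[diag_[, 2]] + x[diag_[, 3]] + x[diag_[, 4]])
    delta <- max(abs(new - x[idx]))
    x[idx] <- new
    if (delta < tol) break
  }
  clamp(x, 0, 255)
}

#' Inpaint masked pixels by iterated diffusion
#'
#' Each channel is repeatedly convolved with a normalized 3x3 diffusion
#' kernel; after every pass unmasked pixels are reset to their original
#' values, so only masked pixels move. Iteration stops at the cap or when the
#' largest per-pass change drops below 0.1 gray level. Unmasked pixels are
#' bit-identical to the input, and inpainted values obey the discrete maximum
#' principle (they stay within the range of the mask's boundary ring).
#'
#' @param image a [fundus_image()].
#' @param mask logical matrix of pixels to reconstruct (same size as image).
#' @param iterations iteration cap.
#' @return a new [fundus_image()].
#' @export
inpaint <- function(image, mask, iterations = 100) {
  stopifnot(inherits(image, "fundus_image"))
  if (!identical(dim(mask), c(image$height, image$width)))
    stopf("mask dimensions must match the image")
  if (all(mask)) stopf("all-true mask: no boundary information to inpaint from")
  px <- array(0, dim(image$pixels))
  for (ch in 1:3)
    px[, , ch] <- round(inpaint_channel(image$pixels[, , ch] * 1.0, mask,
                                        iterations = iterations))
  fundus_image(px, profile = image$profile)
}
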