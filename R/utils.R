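# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Round half away from zero
#'
#' Deterministic half-up rounding used for all printed percentages; base R's
#' `round()` rounds half to even, which does not match the convention of the
#' reported tables (e.g. 256/343 -> 74.6).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# Disk-shaped structuring element with the given pixel radius.
disk_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

# 3x3 box brush used for 8-neighbourhood dilation (adjacency tests).
box3 <- function() matrix(1, 3, 3)

dilate8 <- function(mask) {
  EBImage::dilate(mask * 1, box3()) > 0.5
}

erode8 <- function(mask) {
  EBImage::erode(mask * 1, box3()) > 0.5
}

# Label connected components (8-connectivity); returns integer matrix.
label_components <- function(mask) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(mask * 1)
  matrix(as.integer(lab), nrow(mask), ncol(mask))
}

# Largest connected component of a logical mask (empty mask passes through).
largest_component <- function(mask, tie_center = NULL) {
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L && !is.null(tie_center)) {
    d <- vapply(best, function(i) {
      ctr <- mask_centroid(lab == i)
      sqrt(sum((ctr - tie_center)^2))
    }, numeric(1))
    best <- best[which.min(d)]
  } else {
    best <- best[1L]
  }
  lab == best
}

# Centroid of a logical mask in 0-based (row, col) coordinates.
mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(c(NA_real_, NA_real_))
  c(mean(idx[, 1]) - 1, mean(idx[, 2]) - 1)
}

# Dice overlap of two logical masks.

#' Dice similarity coefficient
#'
#' @param a,b logical masks of identical dimensions.
#' @return Dice coefficient in \[0, 1\]; 1 when both masks are empty.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Derive a reproducible sub-seed (kept below 2^31).
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}
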