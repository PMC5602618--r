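#' @title Cup-to-disc ratio metrics
#' @description The clinical endpoints: horizontal and vertical cup-to-disc
#'   ratios computed from the furthest two pixels of each mask along the
#'   respective axis, plus pixel-count areas and mean-coordinate centroids.
#' @name cdr-metrics
NULL

#' Horizontal extent of a mask
#'
#' The furthest two pixels horizontally: minimum and maximum column index of
#' any true pixel, with the inclusive extent `max - min + 1`.
#'
#' @param mask non-empty logical matrix.
#' @return list with 0-based `min`, `max` and `extent` in pixels.
#' @export
horizontal_extent <- function(mask) {
  cols <- which(colSums(mask) > 0)
  if (!length(cols)) stopf("extent of an empty mask is undefined")
  list(min = min(cols) - 1L, max = max(cols) - 1L,
       extent = max(cols) - min(cols) + 1L)
}

#' Vertical extent of a mask
#'
#' @param mask non-empty logical matrix.
#' @return list with 0-based `min`, `max` and `extent` in pixels.
#' @export
vertical_extent <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  if (!length(rows)) stopf("extent of an empty mask is undefined")
  list(min = min(rows) - 1L, max = max(rows) - 1L,
       extent = max(rows) - min(rows) + 1L)
}

#' Horizontal cup-to-disc ratio
#'
#' Ratio of the cup's horizontal extent to the disc's. The ratio is not
#' clipped at 1: a cup wider than its disc signals a segmentation failure and
#' is surfaced to the evaluation stage rather than silently truncated.
#'
#' @param disc,cup non-empty logical masks.
#' @return unitless ratio.
#' @export
hcdr <- function(disc, cup) {
  horizontal_extent(cup)$extent / horizontal_extent(disc)$extent
}

#' Vertical cup-to-disc ratio
#'
#' @param disc,cup non-empty logical masks.
#' @return unitless ratio.
#' @export
vcdr <- function(disc, cup) {
  vertical_extent(cup)$extent / vertical_extent(disc)$extent
}

#' Compute the six region parameters from disc and cup masks
#'
#' Areas are pixel counts; centroids are arithmetic means of member-pixel
#' coordinates (0-based float). With an empty cup, areas and centroid are
#' reported as 0/NA and the CDRs are flagged absent (NA).
#'
#' @param disc non-empty logical mask.
#' @param cup logical mask (may be empty).
#' @return a [region_params()].
#' @export
region_params_from_masks <- function(disc, cup) {
  if (!any(disc)) stopf("disc mask is empty")
  if (!any(cup)) {
    return(region_params(sum(disc), mask_centroid(disc), 0,
                         c(NA_real_, NA_real_), NA_real_, NA_real_))
  }
  region_params(sum(disc), mask_centroid(disc), sum(cup), mask_centroid(cup),
                hcdr(disc, cup), vcdr(disc, cup))
}

#' Append algorithm markings to a marking table
#'
#' Adds rows with `grader_id = "algorithm"` holding the automatic region
#' parameters for the given images.
#'
#' @param tbl marking table data.frame (may be empty but with the canonical
#'   columns).
#' @param image_ids character vector of image ids.
#' @param params list of [region_params()] parallel to `image_ids`.
#' @return the augmented, validated marking table.
#' @export
append_algorithm_markings <- function(tbl, image_ids, params) {
  stopifnot(length(image_ids) == length(params))
  rows <- mapply(function(id, rp) params_row(id, "algorithm", rp),
                 image_ids, params, SIMPLIFY = FALSE)
  validate_markings(rbind(tbl, do.call(rbind, rows)))
}
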