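#' @title Domain types and IO for fundus images and grader marking tables
#' @description Shared conventions: all raster coordinates are 0-based
#'   `(row, col)`; region-of-interest windows are half-open; masks are logical
#'   matrices in the row/column frame of the image they annotate.
#' @name core-model
NULL

#' Construct a fundus image
#'
#' A fundus image is a 3-channel 8-bit raster tagged with an acquisition
#' quality profile. The profile is set explicitly by the caller (never
#' inferred): `"low_quality"` images (nonmydriatic cameras) are routed through
#' the double level-set disc segmentation path.
#'
#' @param pixels integer array `height x width x 3` with values in 0..255, or
#'   a single matrix which is replicated to three channels.
#' @param profile `"high_quality"` or `"low_quality"`.
#' @return object of class `fundus_image` with fields `pixels`, `height`,
#'   `width`, `profile`.
#' @export
fundus_image <- function(pixels, profile = c("high_quality", "low_quality")) {
  profile <- match.arg(profile)
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stopf("pixels must be a height x width x 3 array")
  if (dim(pixels)[1] < 64L || dim(pixels)[2] < 64L)
    stopf("image must be at least 64 x 64 pixels")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stopf("channel values must lie in [0, 255]")
  structure(
    list(pixels = array(as.integer(round(pixels)), dim(pixels)),
         height = dim(pixels)[1], width = dim(pixels)[2], profile = profile),
    class = "fundus_image")
}

#' @export
print.fundus_image <- function(x, ...) {
  cat(sprintf("<fundus_image> %d x %d, profile=%s\n", x$height, x$width, x$profile))
  invisible(x)
}

#' Extract the green channel as a numeric matrix (0-255)
#'
#' The green channel carries the best vessel/disc contrast in colour fundus
#' photographs and is the working channel of the whole pipeline.
#'
#' @param image a `fundus_image`.
#' @return numeric matrix `height x width`.
#' @export
green_channel <- function(image) {
  stopifnot(inherits(image, "fundus_image"))
  matrix(as.numeric(image$pixels[, , 2]), image$height, image$width)
}

#' Read a fundus image from PNG/TIFF/JPEG
#'
#' 8-bit images are read losslessly. 16-bit rasters are rescaled to 0-255 by
#' integer division of the full 16-bit range. Single-channel images are
#' replicated to three channels with a warning.
#'
#' @param path file path.
#' @param profile quality profile to tag the image with.
#' @return a [fundus_image()].
#' @export
read_image <- function(path, profile = "high_quality") {
  if (!file.exists(path)) stopf("cannot read image: %s", path)
  img <- EBImage::readImage(path)
  d <- dim(img)
  a <- EBImage::imageData(img)
  if (length(d) == 2L) {
    warning("single-channel image replicated to 3 channels: ", basename(path))
    a <- array(rep(a, 3L), c(d, 3L))
  } else if (d[3] > 3L) {
    a <- a[, , 1:3] # drop alpha
  } else if (d[3] == 2L) {
    warning("single-channel image replicated to 3 channels: ", basename(path))
    a <- array(rep(a[, , 1], 3L), c(d[1:2], 3L))
  }
  v8 <- a * 255
  if (max(abs(v8 - round(v8))) > 1e-6) {
    # 16-bit source: recover raw values and integer-divide the full range
    v8 <- round(a * 65535) %/% 256
  } else {
    v8 <- round(v8)
  }
  # EBImage stores (x, y, channel); transpose to (row, col, channel)
  px <- aperm(v8, c(2, 1, 3))
  fundus_image(px, profile = profile)
}

#' Write a fundus image as an 8-bit raster
#'
#' @param image a `fundus_image`.
#' @param path output path; format chosen from the extension (png/tiff/jpeg).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "fundus_image"))
  a <- aperm(image$pixels, c(2, 1, 3)) / 255
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  invisible(path)
}

#' Write a binary mask as a PNG
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(mask * 1)), path)
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#'
#' @param path PNG path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  a <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(a)) == 3L) a <- a[, , 1]
  t(a) > 0.5
}

#' Region-of-interest window
#'
#' Half-open window with 0-based top-left offsets, fully contained in its
#' parent image.
#'
#' @param row0,col0 0-based offsets of the top-left corner.
#' @param n_rows,n_cols window extent in pixels (must be positive).
#' @return object of class `roi_window`.
#' @export
roi_window <- function(row0, col0, n_rows, n_cols) {
  if (n_rows <= 0 || n_cols <= 0) stopf("ROI extent must be positive")
  if (row0 < 0 || col0 < 0) stopf("ROI offsets must be non-negative")
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
            class = "roi_window")
}

# Crop a matrix to an ROI (1-based internal indexing).
roi_crop <- function(mat, roi) {
  if (roi$row0 + roi$n_rows > nrow(mat) || roi$col0 + roi$n_cols > ncol(mat))
    stopf("ROI exceeds parent dimensions")
  mat[(roi$row0 + 1L):(roi$row0 + roi$n_rows),
      (roi$col0 + 1L):(roi$col0 + roi$n_cols), drop = FALSE]
}

# Paste an ROI-frame matrix back into a full-size frame filled with `fill`.
roi_uncrop <- function(mat, roi, height, width, fill = FALSE) {
  out <- matrix(fill, height, width)
  out[(roi$row0 + 1L):(roi$row0 + roi$n_rows),
      (roi$col0 + 1L):(roi$col0 + roi$n_cols)] <- mat
  out
}

#' Assemble the six per-image region parameters
#'
#' @param disc_area,cup_area pixel counts.
#' @param disc_centroid,cup_centroid length-2 `(row, col)` in 0-based float
#'   pixels.
#' @param hcdr,vcdr unitless cup-to-disc ratios.
#' @return object of class `region_params`.
#' @export
region_params <- function(disc_area, disc_centroid, cup_area, cup_centroid,
                          hcdr, vcdr) {
  if (disc_area < 0 || cup_area < 0) stopf("areas must be non-negative")
  structure(list(disc_area = disc_area,
                 disc_centroid = as.numeric(disc_centroid),
                 cup_area = cup_area,
                 cup_centroid = as.numeric(cup_centroid),
                 hcdr = hcdr, vcdr = vcdr),
            class = "region_params")
}

marking_columns <- c("image_id", "grader_id", "disc_area",
                     "disc_centroid_row", "disc_centroid_col", "cup_area",
                     "cup_centroid_row", "cup_centroid_col", "hcdr", "vcdr")

#' Validate a marking table
#'
#' A marking table holds one row of region parameters per (image, grader)
#' pair; grader ids are `"1"`..`"6"` for the manual graders plus optionally
#' `"algorithm"`.
#'
#' @param tbl data.frame with the columns listed under [read_markings()].
#' @return the validated data.frame (grader ids as character).
#' @export
validate_markings <- function(tbl) {
  missing <- setdiff(marking_columns, names(tbl))
  if (length(missing))
    stopf("marking table is missing columns: %s", paste(missing, collapse = ", "))
  tbl$image_id <- as.character(tbl$image_id)
  tbl$grader_id <- as.character(tbl$grader_id)
  key <- paste(tbl$image_id, tbl$grader_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stopf("duplicate (image_id, grader_id) record: (%s)",
          gsub("\r", ", ", d, fixed = TRUE))
  }
  if (any(tbl$disc_area < 0, na.rm = TRUE) || any(tbl$cup_area < 0, na.rm = TRUE))
    stopf("negative area in marking table")
  tbl[, marking_columns]
}

#' Read a grader marking table (CSV or JSON)
#'
#' Expected columns: `image_id, grader_id, disc_area, disc_centroid_row,
#' disc_centroid_col, cup_area, cup_centroid_row, cup_centroid_col, hcdr,
#' vcdr`. Duplicate (image, grader) keys and negative areas are rejected.
#'
#' @param path file path ending in `.csv` or `.json`.
#' @return validated data.frame.
#' @export
read_markings <- function(path) {
  if (!file.exists(path)) stopf("cannot read markings: %s", path)
  tbl <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  validate_markings(tbl)
}

#' Write a grader marking table
#'
#' Columns are emitted in the fixed canonical order so that rewrites are
#' byte-stable.
#'
#' @param tbl marking table data.frame.
#' @param path output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_markings <- function(tbl, path) {
  tbl <- validate_markings(tbl)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(tbl, path, digits = NA, dataframe = "rows")
  } else {
    utils::write.csv(tbl, path, row.names = FALSE)
  }
  invisible(path)
}
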