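#' @title Multi-grader evaluation protocol
#' @description Quantifies inter-grader variability and screens out
#'   unreliable images before scoring the automatic system: per-image sample
#'   SDs across graders per parameter, mean-SD outlier thresholds (the CDR
#'   threshold is the fixed constant 0.075), iterative marking-level outlier
#'   detection, image-elimination rules, accuracy percentages and pairwise
#'   agreement counts.
#' @name grader-eval
NULL

#' Parameter sets per analysis
#'
#' The HCDR analysis screens on disc area/centroid, cup area/centroid and
#' HCDR; the VCDR analysis swaps HCDR for VCDR; the final consolidated
#' analysis uses all six parameters.
#'
#' @param analysis `"hcdr"`, `"vcdr"` or `"final"`.
#' @return character vector of parameter ids.
#' @export
analysis_params <- function(analysis = c("hcdr", "vcdr", "final")) {
  switch(match.arg(analysis),
         hcdr = c("disc_area", "disc_centroid", "cup_area", "cup_centroid", "hcdr"),
         vcdr = c("disc_area", "disc_centroid", "cup_area", "cup_centroid", "vcdr"),
         final = param_groups)
}

#' Unbiased sample standard deviation
#'
#' The n-1 denominator convention: it reproduces the protocol's printed
#' per-image SD examples, which the population convention does not.
#'
#' @param values numeric vector of length >= 2.
#' @return scalar SD.
#' @export
sample_sd <- function(values) {
  if (length(values) < 2L) stopf("sample SD needs at least 2 values")
  stats::sd(values)
}

#' Combined SD of 2-d centroid markings
#'
#' Sample SD of each coordinate separately, combined as the Euclidean norm,
#' giving a single pixel-valued spread measure.
#'
#' @param points matrix with columns `(row, col)`, >= 2 rows.
#' @return scalar SD in pixels.
#' @export
centroid_sd <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stopf("centroid SD needs at least 2 points")
  sqrt(stats::sd(points[, 1])^2 + stats::sd(points[, 2])^2)
}

# Per-image spread of one parameter for a set of grader rows.
param_spread <- function(rows, param) {
  switch(param,
    disc_area = sample_sd(rows$disc_area),
    cup_area = sample_sd(rows$cup_area),
    disc_centroid = centroid_sd(cbind(rows$disc_centroid_row, rows$disc_centroid_col)),
    cup_centroid = centroid_sd(cbind(rows$cup_centroid_row, rows$cup_centroid_col)),
    hcdr = sample_sd(rows$hcdr),
    vcdr = sample_sd(rows$vcdr))
}

#' Mean-SD outlier thresholds
#'
#' For every parameter, the threshold is the mean over images of the
#' per-image SD among the manual graders; it is the judge deciding whether an
#' image's spread flags outlying markings. The HCDR/VCDR thresholds default
#' to the fixed protocol constant 0.075 (set `override_cdr = NULL` to use the
#' empirical means instead).
#'
#' @param markings marking table (manual graders; algorithm rows ignored).
#' @param override_cdr fixed CDR threshold or `NULL`.
#' @return named list of thresholds (class `sd_thresholds`).
#' @export
sd_thresholds <- function(markings, override_cdr = 0.075) {
  markings <- validate_markings(markings)
  manual <- markings[markings$grader_id != "algorithm", ]
  imgs <- split(manual, manual$image_id)
  thr <- lapply(param_groups, function(p) {
    mean(vapply(imgs, function(rows) {
      if (nrow(rows) < 2L) return(NA_real_)
      param_spread(rows, p)
    }, numeric(1)), na.rm = TRUE)
  })
  names(thr) <- param_groups
  if (!is.null(override_cdr)) {
    thr$hcdr <- override_cdr
    thr$vcdr <- override_cdr
  }
  structure(thr, class = "sd_thresholds")
}

#' Calibrated protocol threshold constants per dataset profile
#'
#' The screening protocol's published calibration constants: the CDR
#' threshold 0.075 everywhere; a 3000-px cup-area threshold for the
#' low-resolution (2376-wide) profile; an 8000-px disc-area and 10-px
#' centroid threshold for the high-resolution (2743-wide) profile.
#' Parameters with no published constant are `NA` and are meant to be filled
#' from the empirical mean SDs of [sd_thresholds()].
#'
#' @param profile `"binrushed"`, `"magrabi"` or `"messidor"`.
#' @return an `sd_thresholds` list (NAs where no constant is published).
#' @export
protocol_thresholds <- function(profile = c("binrushed", "magrabi", "messidor")) {
  profile <- match.arg(profile)
  thr <- as.list(rep(NA_real_, 6))
  names(thr) <- param_groups
  thr$hcdr <- 0.075
  thr$vcdr <- 0.075
  if (profile == "binrushed") thr$cup_area <- 3000
  if (profile == "magrabi") {
    thr$disc_area <- 8000
    thr$disc_centroid <- 10
    thr$cup_centroid <- 10
  }
  structure(thr, class = "sd_thresholds")
}

# Spread of a value set (vector or 2-column matrix).
value_spread <- function(values) {
  if (is.matrix(values)) centroid_sd(values) else sample_sd(values)
}

#' Detect outlying markings by iterative leave-one-out
#'
#' While the spread of the remaining values exceeds the threshold and more
#' than three values remain, the value whose removal most reduces the
#' remaining spread is flagged and removed (ties broken by larger absolute
#' deviation from the mean, then by lower grader id). The remaining set never
#' drops below three values.
#'
#' @param values numeric vector, or 2-column matrix for centroid parameters.
#' @param threshold spread threshold.
#' @param ids grader ids parallel to `values`; defaults to `"1"`, `"2"`, ...
#' @return character vector of flagged ids (possibly empty).
#' @export
detect_outliers <- function(values, threshold, ids = NULL) {
  n <- if (is.matrix(values)) nrow(values) else length(values)
  if (n < 3L) stopf("outlier detection needs at least 3 values")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  take <- function(v, keep) if (is.matrix(v)) v[keep, , drop = FALSE] else v[keep]
  flagged <- character(0)
  keep <- seq_len(n)
  repeat {
    cur <- take(values, keep)
    if (value_spread(cur) <= threshold || length(keep) <= 3L) break
    sds <- vapply(seq_along(keep), function(i)
      value_spread(take(values, keep[-i])), numeric(1))
    cand <- which(sds == min(sds))
    if (length(cand) > 1L) {
      dev <- if (is.matrix(values)) {
        ctr <- colMeans(cur)
        sqrt(rowSums((cur[cand, , drop = FALSE] -
                        matrix(ctr, length(cand), 2, byrow = TRUE))^2))
      } else abs(cur[cand] - mean(cur))
      cand <- cand[dev == max(dev)]
      if (length(cand) > 1L)
        cand <- cand[order(ids[keep[cand]])][1L]
    }
    cand <- cand[1L]
    flagged <- c(flagged, ids[keep[cand]])
    keep <- keep[-cand]
  }
  flagged
}

# Extract the value set of one parameter for detect_outliers.
param_values <- function(rows, param) {
  switch(param,
    disc_area = rows$disc_area,
    cup_area = rows$cup_area,
    disc_centroid = cbind(rows$disc_centroid_row, rows$disc_centroid_col),
    cup_centroid = cbind(rows$cup_centroid_row, rows$cup_centroid_col),
    hcdr = rows$hcdr,
    vcdr = rows$vcdr)
}

# Elimination rule on per-parameter outlier counts: >= 3 flags on one
# parameter, or >= 4 flags total with >= 2 sharing a parameter.
eliminate_image <- function(counts) {
  total <- sum(counts)
  max(counts) >= 3L || (total >= 4L && max(counts) >= 2L)
}

#' Evaluate one entity (grader or algorithm) against the panel
#'
#' Per image the six manual markings -- plus the algorithm's marking when the
#' algorithm is the evaluated entity -- are screened per analysis parameter
#' with [detect_outliers()]; images are eliminated by the outlier-count
#' rules; not-localized images are excluded from testing. On the remaining
#' (tested) images the entity is accurate iff none of its markings is
#' flagged on any analysis parameter.
#'
#' @param markings marking table with manual graders `"1"..."6"` and
#'   optionally `"algorithm"` rows.
#' @param entity grader id or `"algorithm"`.
#' @param params character vector of analysis parameters (see
#'   [analysis_params()]).
#' @param thresholds an [sd_thresholds()] list.
#' @param not_localized character vector of image ids the disc stage failed
#'   on; images lacking an algorithm row are treated likewise when the
#'   algorithm is evaluated.
#' @return data.frame per image: `image_id`, `eliminated`, `not_localized`,
#'   `tested`, `flagged` (entity flagged on any parameter), `accurate`.
#' @export
evaluate_entity <- function(markings, entity, params, thresholds,
                            not_localized = character(0)) {
  markings <- validate_markings(markings)
  entity <- as.character(entity)
  if (!entity %in% markings$grader_id)
    stopf("entity '%s' not present in the marking table", entity)
  use_algo <- entity == "algorithm"
  imgs <- split(markings, markings$image_id)
  res <- lapply(names(imgs), function(id) {
    tab <- imgs[[id]]
    manual <- tab[tab$grader_id != "algorithm", ]
    manual <- manual[order(as.integer(manual$grader_id)), ]
    rows <- manual
    if (use_algo) {
      arow <- tab[tab$grader_id == "algorithm", ]
      if (nrow(arow) == 0L) {
        return(data.frame(image_id = id, eliminated = FALSE,
                          not_localized = TRUE, tested = FALSE,
                          flagged = NA, accurate = NA))
      }
      rows <- rbind(manual, arow)
    }
    nl <- id %in% not_localized
    flags <- lapply(params, function(p)
      detect_outliers(param_values(rows, p), thresholds[[p]],
                      ids = rows$grader_id))
    names(flags) <- params
    counts <- vapply(flags, length, integer(1))
    elim <- eliminate_image(counts)
    tested <- !elim && !nl
    flagged <- any(vapply(flags, function(f) entity %in% f, logical(1)))
    data.frame(image_id = id, eliminated = elim && !nl, not_localized = nl,
               tested = tested, flagged = flagged,
               accurate = tested && !flagged)
  })
  do.call(rbind, res)
}

#' Accuracy percentage (truncated to one decimal)
#'
#' Percentages are truncated, not rounded: the protocol's printed tables
#' follow 82/127 -> 64.5, 148/194 -> 76.2, 149/169 -> 88.1, which half-up
#' rounding would print as 64.6, 76.3 and 88.2.
#'
#' @param accurate,tested image counts.
#' @return percentage truncated to one decimal.
#' @export
accuracy_percentage <- function(accurate, tested) {
  trunc_pct(100 * accurate / tested)
}

# Truncate a percentage to one decimal (epsilon guards float representation).
trunc_pct <- function(x) floor(x * 10 + 1e-9) / 10

#' Accuracy table across graders and algorithm
#'
#' One column per manual grader plus the algorithm (when present), with rows
#' `total`, `removed`, `not_localized`, `tested`, `accurate`, `percentage`.
#'
#' @inheritParams evaluate_entity
#' @param analysis `"hcdr"`, `"vcdr"` or `"final"`.
#' @return data.frame (rows as above, columns per entity).
#' @export
accuracy_table <- function(markings, thresholds, analysis = "hcdr",
                           not_localized = character(0)) {
  markings <- validate_markings(markings)
  params <- analysis_params(analysis)
  graders <- sort(unique(markings$grader_id[markings$grader_id != "algorithm"]))
  entities <- c(graders, intersect("algorithm", unique(markings$grader_id)))
  total <- length(unique(markings$image_id))
  cols <- lapply(entities, function(e) {
    ev <- evaluate_entity(markings, e, params, thresholds, not_localized)
    tested <- sum(ev$tested)
    acc <- sum(ev$accurate, na.rm = TRUE)
    c(total = total, removed = sum(ev$eliminated, na.rm = TRUE),
      not_localized = sum(ev$not_localized), tested = tested, accurate = acc,
      percentage = accuracy_percentage(acc, tested))
  })
  out <- as.data.frame(cols, optional = TRUE)
  names(out) <- entities
  out
}

#' Pairwise agreement matrix
#'
#' Entry (a, b) counts images on which both entities are unflagged on every
#' analysis parameter and the image is neither eliminated nor not-localized
#' under either entity's evaluation; the diagonal holds the total image
#' count. A `total` attribute row sums each entity's off-diagonal agreements.
#'
#' @inheritParams accuracy_table
#' @return square matrix with entity dimnames and attribute `totals`.
#' @export
agreement_matrix <- function(markings, thresholds, analysis = "hcdr",
                             not_localized = character(0)) {
  markings <- validate_markings(markings)
  params <- analysis_params(analysis)
  graders <- sort(unique(markings$grader_id[markings$grader_id != "algorithm"]))
  entities <- c(graders, intersect("algorithm", unique(markings$grader_id)))
  total <- length(unique(markings$image_id))
  evs <- lapply(entities, function(e)
    evaluate_entity(markings, e, params, thresholds, not_localized))
  names(evs) <- entities
  # per entity: images accepted under its own evaluation (tested and unflagged)
  ok <- vapply(evs, function(ev) {
    v <- ev$tested & !ev$flagged
    v[is.na(v)] <- FALSE
    v
  }, logical(nrow(evs[[1]])))
  ok <- matrix(ok, ncol = length(entities))
  n <- length(entities)
  m <- matrix(0L, n, n, dimnames = list(entities, entities))
  for (i in seq_len(n))
    for (j in seq_len(n))
      m[i, j] <- if (i == j) total else sum(ok[, i] & ok[, j])
  attr(m, "totals") <- rowSums(m) - diag(m)
  m
}
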