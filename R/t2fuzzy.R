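#' @title Interval Type-II fuzzy-entropy multilevel thresholding
#' @description Selects k gray-level thresholds by maximizing a sum of
#'   within-class Shannon entropies computed on fuzzy class masses. Each of
#'   the k+1 classes carries a triangular primary membership centred between
#'   its boundaries; widening and narrowing the triangle by a
#'   footprint-of-uncertainty width gives upper and lower memberships whose
#'   average defines the interval Type-II class membership. The k thresholds
#'   are searched with a DE/rand/1/bin Differential Evolution optimizer; an
#'   exhaustive-search oracle is provided for verification at small scale.
#' @name t2fuzzy
NULL

#' Gray-level histogram of an 8-bit image
#'
#' @param gray numeric matrix with values in 0-255.
#' @return integer vector of 256 counts (gray levels 0..255).
#' @export
gray_histogram <- function(gray) {
  v <- as.integer(round(gray))
  if (any(v < 0 | v > 255)) stopf("gray values must lie in [0, 255]")
  tabulate(v + 1L, nbins = 256L)
}

#' Construct a validated threshold set
#'
#' @param thresholds strictly increasing gray levels in (0, 255).
#' @return object of class `threshold_set` with fields `k` and `thresholds`.
#' @export
threshold_set <- function(thresholds) {
  t <- as.numeric(thresholds)
  if (length(t) < 1L) stopf("at least one threshold required")
  if (any(diff(t) <= 0)) stopf("thresholds must be strictly increasing")
  if (min(t) <= 0 || max(t) >= 255) stopf("thresholds must lie in (0, 255)")
  structure(list(k = length(t), thresholds = t), class = "threshold_set")
}

# Interval memberships: 256 x (k+1) matrix of averaged upper/lower triangular
# memberships, normalized across classes at every gray level. Levels where
# all primary memberships vanish (exactly at a threshold when fou_width = 0)
# fall back to the hard label rule (label = number of thresholds <= level).
t2_memberships <- function(thresholds, fou_width) {
  k <- length(thresholds)
  b <- c(-1, thresholds, 256)
  g <- 0:255
  M <- matrix(0, 256L, k + 1L)
  for (j in seq_len(k + 1L)) {
    lo <- b[j]; hi <- b[j + 1]
    ctr <- (lo + hi) / 2
    half <- (hi - lo) / 2
    upper <- pmax(0, 1 - abs(g - ctr) / (half + fou_width))
    lower <- pmax(0, 1 - abs(g - ctr) / max(half - fou_width, 0.5))
    M[, j] <- (upper + lower) / 2
  }
  rs <- rowSums(M)
  zero <- rs == 0
  if (any(zero)) {
    lab <- findInterval(g[zero], thresholds) + 1L
    M[cbind(which(zero), lab)] <- 1
    rs[zero] <- 1
  }
  M / rs
}

#' Interval Type-II fuzzy entropy of a threshold set
#'
#' For each class the fuzzy mass at every gray level is the histogram
#' frequency weighted by the class's interval membership; the class entropy
#' is the Shannon entropy `-sum(q log q)` of those masses normalized within
#' the class, and the score is the sum over classes (higher is better). A
#' class with no membership mass makes the threshold set infeasible
#' (score `-Inf`). The score is invariant to histogram scaling.
#'
#' @param hist 256-bin histogram (counts for gray levels 0..255).
#' @param ts a [threshold_set()] or a numeric vector of thresholds.
#' @param fou_width footprint-of-uncertainty half-width in gray levels.
#' @return scalar score.
#' @export
t2_fuzzy_entropy <- function(hist, ts, fou_width = 10) {
  if (length(hist) != 256L) stopf("hist must have 256 bins")
  tot <- sum(hist)
  if (tot <= 0) stopf("empty histogram")
  thr <- if (inherits(ts, "threshold_set")) ts$thresholds else as.numeric(ts)
  p <- hist / tot
  M <- t2_memberships(thr, fou_width)
  q <- p * M
  P <- colSums(q)
  if (any(P < 1e-12)) return(-Inf)
  score <- 0
  for (j in seq_along(P)) {
    qq <- q[, j][q[, j] > 0] / P[j]
    score <- score - sum(qq * log(qq))
  }
  score
}

#' Exhaustive-search threshold oracle
#'
#' Enumerates every strictly increasing threshold combination on the given
#' candidate grid and returns the best-scoring set. Intended as the
#' independent reference for [de_optimize()] at small k/grid sizes.
#'
#' @param hist 256-bin histogram.
#' @param k number of thresholds (1..3 supported).
#' @param fou_width footprint-of-uncertainty width.
#' @param grid candidate gray levels (default 1..254).
#' @return list with `thresholds` (integer vector) and `score`.
#' @export
exhaustive_thresholds <- function(hist, k, fou_width = 10, grid = 1:254) {
  if (k > 3) stopf("exhaustive search supports k <= 3")
  combos <- utils::combn(grid, k)
  best <- -Inf; best_t <- NULL
  for (i in seq_len(ncol(combos))) {
    s <- t2_fuzzy_entropy(hist, combos[, i], fou_width)
    if (s > best) { best <- s; best_t <- combos[, i] }
  }
  list(thresholds = as.integer(best_t), score = best)
}

#' Differential Evolution parameters
#'
#' Standard DE settings; the seed must be supplied explicitly so that every
#' optimization in the pipeline is reproducible.
#'
#' @param pop_size population size (>= 4).
#' @param generations number of generations.
#' @param F differential weight in (0, 2].
#' @param CR crossover rate in \[0, 1\].
#' @param seed integer RNG seed.
#' @return object of class `de_params`.
#' @export
de_params <- function(pop_size = 30, generations = 100, F = 0.5, CR = 0.9,
                      seed) {
  if (pop_size < 4) stopf("population size must be >= 4")
  if (F <= 0 || F > 2) stopf("F must lie in (0, 2]")
  if (CR < 0 || CR > 1) stopf("CR must lie in [0, 1]")
  if (missing(seed)) stopf("an explicit seed is required")
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 F = F, CR = CR, seed = as.integer(seed)),
            class = "de_params")
}

#' Optimize thresholds with DE/rand/1/bin
#'
#' Evolves k-dimensional real vectors in \[1, 254\]; candidates are sorted and
#' rounded to integers at evaluation (duplicate levels are infeasible).
#' Deterministic for a given seed.
#'
#' @param hist 256-bin histogram.
#' @param k number of thresholds; must not exceed the number of distinct
#'   occupied gray levels minus one.
#' @param params a [de_params()].
#' @param fou_width footprint-of-uncertainty width in gray levels.
#' @return a [threshold_set()] with an added `score` field.
#' @export
de_optimize <- function(hist, k, params, fou_width = 10) {
  stopifnot(inherits(params, "de_params"))
  occupied <- sum(hist > 0)
  if (k > occupied - 1) stopf("k = %d infeasible: only %d occupied gray levels", k, occupied)
  evalcand <- function(v) {
    t <- sort(round(v))
    if (anyDuplicated(t)) return(-Inf)
    t2_fuzzy_entropy(hist, t, fou_width)
  }
  np <- params$pop_size
  withr::with_seed(params$seed, {
    pop <- matrix(stats::runif(k * np, 1, 254), nrow = k)
    scores <- apply(pop, 2, evalcand)
    for (gen in seq_len(params$generations)) {
      for (i in seq_len(np)) {
        r <- sample(setdiff(seq_len(np), i), 3L)
        v <- pop[, r[1]] + params$F * (pop[, r[2]] - pop[, r[3]])
        v <- clamp(v, 1, 254)
        jrand <- sample.int(k, 1L)
        cross <- stats::runif(k) < params$CR
        cross[jrand] <- TRUE
        trial <- ifelse(cross, v, pop[, i])
        s <- evalcand(trial)
        if (s > scores[i]) { pop[, i] <- trial; scores[i] <- s }
      }
    }
  })
  best <- which.max(scores)
  ts <- threshold_set(sort(round(pop[, best])))
  ts$score <- scores[best]
  ts
}

#' Apply thresholds to a gray image
#'
#' Pixel label = number of thresholds less than or equal to the pixel value,
#' so k thresholds produce k+1 classes with label 0 darkest; a pixel exactly
#' equal to a threshold joins the upper class.
#'
#' @param gray numeric matrix with values in 0-255.
#' @param ts a [threshold_set()] or numeric vector of thresholds.
#' @return integer label matrix with attribute `k`.
#' @export
apply_thresholds <- function(gray, ts) {
  thr <- if (inherits(ts, "threshold_set")) ts$thresholds else sort(as.numeric(ts))
  lab <- matrix(findInterval(gray, thr), nrow(gray), ncol(gray))
  attr(lab, "k") <- length(thr)
  lab
}
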