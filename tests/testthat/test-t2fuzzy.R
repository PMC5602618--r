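test_that("two-delta histogram: every separating threshold is optimal and equivalent", {
  h <- integer(256); h[10 + 1] <- 500L; h[200 + 1] <- 500L
  scores <- vapply(1:254, function(t) t2_fuzzy_entropy(h, t, fou_width = 0),
                   numeric(1))
  inside <- scores[11:199]
  expect_lt(diff(range(inside)), 1e-12)           # constant over the gap
  expect_true(all(scores[c(1:9, 201:254)] < min(inside)))  # maximal vs outside
})

test_that("zero footprint width degenerates to the Type-I fuzzy entropy", {
  # independent Type-I computation: primary triangular memberships only,
  # normalized per level, Shannon entropy of within-class masses
  type1 <- function(hist, thr) {
    p <- hist / sum(hist)
    b <- c(-1, thr, 256); g <- 0:255
    M <- sapply(seq_len(length(thr) + 1), function(j) {
      ctr <- (b[j] + b[j + 1]) / 2
      half <- (b[j + 1] - b[j]) / 2
      pmax(0, 1 - abs(g - ctr) / half)
    })
    rs <- rowSums(M)
    zero <- rs == 0
    if (any(zero)) {
      M[cbind(which(zero), findInterval(g[zero], thr) + 1L)] <- 1
      rs[zero] <- 1
    }
    q <- p * (M / rs)
    sum(apply(q, 2, function(col) {
      P <- sum(col); qq <- col[col > 0] / P
      -sum(qq * log(qq))
    }))
  }
  set.seed(21)
  h <- as.integer(rpois(256, rep(c(5, 60, 10, 90), each = 64)))
  for (thr in list(100, c(64, 128), c(40, 120, 200)))
    expect_equal(t2_fuzzy_entropy(h, thr, fou_width = 0), type1(h, thr),
                 tolerance = 1e-12)
})

test_that("uniform histogram score is symmetric about the middle threshold", {
  h <- rep(10L, 256)
  s <- vapply(1:254, function(t) t2_fuzzy_entropy(h, t, 10), numeric(1))
  expect_lt(max(abs(s - rev(s))), 1e-9)
  expect_equal(which.max(s), 127)
})

test_that("the score is invariant to histogram scaling", {
  set.seed(3)
  h <- as.integer(rpois(256, 20))
  expect_equal(t2_fuzzy_entropy(h, c(80, 170), 10),
               t2_fuzzy_entropy(h * 13L, c(80, 170), 10), tolerance = 1e-12)
})

test_that("empty histograms and invalid threshold sets are rejected", {
  expect_error(t2_fuzzy_entropy(integer(256), 100), "empty")
  expect_error(threshold_set(c(10, 10)), "increasing")
  expect_error(threshold_set(c(0, 10)), "\\(0, 255\\)")
  expect_error(de_params(pop_size = 3, seed = 1), "population")
  expect_error(de_params(pop_size = 10), "seed")
})

test_that("DE matches exhaustive search for k = 1 over the full grid", {
  set.seed(14)
  for (i in 1:3) {
    h <- as.integer(rpois(256, sample(c(2, 40, 80), 256, TRUE)))
    ex <- exhaustive_thresholds(h, 1, 10)
    de <- de_optimize(h, 1, de_params(seed = 100 + i), 10)
    expect_equal(de$score, ex$score, tolerance = 1e-10)
  }
})

test_that("DE separates a three-delta histogram exactly (k = 2)", {
  h <- integer(256); h[c(21, 121, 231)] <- c(300L, 400L, 300L)
  ex <- exhaustive_thresholds(h, 2, fou_width = 0)
  de <- de_optimize(h, 2, de_params(seed = 5), fou_width = 0)
  expect_equal(de$score, ex$score, tolerance = 1e-10)
  # returned classes isolate the three deltas
  lab <- apply_thresholds(matrix(c(20, 120, 230), 1), de)
  expect_equal(as.integer(lab), 0:2)
})

test_that("DE is deterministic under its seed and validates feasibility", {
  h <- integer(256); h[c(11, 101, 201)] <- 100L
  a <- de_optimize(h, 2, de_params(seed = 9))
  b <- de_optimize(h, 2, de_params(seed = 9))
  expect_identical(a$thresholds, b$thresholds)
  expect_error(de_optimize(h, 3, de_params(seed = 9)), "infeasible")
})

test_that("apply_thresholds counts thresholds <= value, giving k+1 classes", {
  g <- matrix(c(50, 150), 1)
  expect_equal(as.integer(apply_thresholds(g, 100)), c(0L, 1L))
  # a pixel equal to a threshold joins the upper class
  expect_equal(as.integer(apply_thresholds(matrix(100), 100)), 1L)
  set.seed(4)
  img <- matrix(sample(0:255, 400, TRUE), 20)
  lab3 <- apply_thresholds(img, c(60, 120, 200))
  expect_true(all(lab3 %in% 0:3))
  lab4 <- apply_thresholds(img, c(50, 100, 150, 200))
  expect_true(all(lab4 %in% 0:4))
  # monotone: brighter pixel never gets a lower label
  o <- order(img)
  expect_true(all(diff(lab3[o]) >= 0))
})
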