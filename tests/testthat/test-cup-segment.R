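make_labels <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- 1L
  attr(lab, "k") <- 1L
  lab
}

test_that("brightest_region drops sub-minimum spots and keeps the largest survivor", {
  m <- matrix(FALSE, 100, 100)
  m[10:16, 10:16] <- TRUE                # 49 px
  m[40:59, 40:54] <- TRUE                # 300 px
  out <- brightest_region(make_labels(m), min_spot = 50)
  expect_equal(sum(out), 300)
  expect_false(any(out[10:16, 10:16]))
  # a component of exactly 50 px survives ("less than 50" are eliminated)
  m2 <- matrix(FALSE, 100, 100); m2[10:19, 10:14] <- TRUE  # 50 px
  expect_equal(sum(brightest_region(make_labels(m2), min_spot = 50)), 50)
  # no pixels in the top class -> empty mask
  lab <- matrix(0L, 20, 20); attr(lab, "k") <- 2L
  expect_equal(sum(brightest_region(lab)), 0)
})

test_that("refine_cup bridges vessel gaps into one component", {
  m <- matrix(FALSE, 60, 60)
  m[20:40, 10:28] <- TRUE
  m[20:40, 32:50] <- TRUE               # 3-px gap at cols 29..31
  v <- matrix(FALSE, 60, 60)
  v[25:35, 29:31] <- TRUE               # vessel covering the gap
  out <- refine_cup(m, v, closing_radius = 2)
  expect_equal(max(fundusCDR:::label_components(out)), 1L)
  expect_gte(sum(out), sum(m))
})

test_that("refine_cup with no vessels and zero closing keeps the largest component", {
  m <- matrix(FALSE, 60, 60)
  m[5:14, 5:14] <- TRUE                  # 100 px
  m[30:49, 30:49] <- TRUE                # 400 px
  none <- matrix(FALSE, 60, 60)
  out <- refine_cup(m, none, closing_radius = 0)
  expect_equal(sum(out), 400)
  # extensive relative to the retained component; empty input stays empty
  expect_gte(sum(refine_cup(m, none, closing_radius = 3)), 400)
  expect_equal(sum(refine_cup(none, none, 2)), 0)
})

test_that("Hough fit recovers analytic circles within a pixel", {
  m <- test_circle(128, c(63.5, 63.5), 40)
  f <- hough_circle_fit(m, 20, 60)
  expect_lte(abs(f$radius - 40), 1)
  expect_lte(max(abs(f$center - c(63.5, 63.5))), 1)
})

test_that("Hough tolerates a missing half-arc (center within 3 px)", {
  m <- test_circle(128, c(63.5, 63.5), 40)
  m[, 65:128] <- FALSE
  f <- hough_circle_fit(m, 20, 60)
  expect_lte(max(abs(f$center - c(63.5, 63.5))), 3)
})

test_that("Hough tolerates boundary jitter (radius within 2 px)", {
  m <- test_circle(128, c(63.5, 63.5), 40)
  b <- which(m & !fundusCDR:::erode8(m), arr.ind = TRUE)
  set.seed(6)
  jb <- b + matrix(sample(-1:1, length(b), TRUE), ncol = 2)
  jm <- matrix(FALSE, 128, 128); jm[jb] <- TRUE
  f <- hough_circle_fit(jm, 20, 60)
  expect_lte(abs(f$radius - 40), 2)
  expect_error(hough_circle_fit(matrix(FALSE, 10, 10), 2, 5), "empty")
})

# radial-gradient blob: the k = 3 top class is a small core, the k = 2 top
# class a larger one, so an area floor between the two fitted areas forces
# exactly one extra loop
gradient_roi <- function() {
  n <- 128
  r <- matrix(0:(n - 1), n, n); c_ <- matrix(0:(n - 1), n, n, byrow = TRUE)
  d <- sqrt((r - 63.5)^2 + (c_ - 63.5)^2)
  img <- matrix(40, n, n)
  blob <- d <= 40
  img[blob] <- 220 - 2.5 * d[blob]
  list(img = img, disc = d <= 55, vessels = matrix(FALSE, n, n))
}

test_that("an undersized loop-1 cup triggers exactly the second loop", {
  fx <- gradient_roi()
  cfg <- cup_config(scale_area_floor = FALSE, area_floor = 1200, seed = 5)
  res <- segment_cup(fx$img, fx$disc, fx$vessels, cfg)
  expect_true(res$success)
  expect_equal(res$loop_used, 2L)
  expect_equal(res$log$loop, 1:2)
  expect_false(res$log$accepted[1])
  expect_lte(res$log$area[1], 1200)
})

test_that("the cascade visits loops 1-4 in order with k 3,2,4,3 and enhancement on,on,off,off", {
  fx <- gradient_roi()
  cfg <- cup_config(scale_area_floor = FALSE, area_floor = 5000, seed = 5)
  res <- segment_cup(fx$img, fx$disc, fx$vessels, cfg)
  expect_false(res$success)
  expect_identical(res$log$loop, 1:4)
  expect_identical(res$log$k, c(3L, 2L, 4L, 3L))
  expect_identical(res$log$enhance, c(TRUE, TRUE, FALSE, FALSE))
  expect_false(any(res$log$accepted))
  expect_identical(cup_loop_configs()$k, c(3L, 2L, 4L, 3L))
})

test_that("a healthy loop-1 cup is accepted immediately and never touches the disc", {
  ph <- suite_phantom(3)
  res <- segment_fundus(ph$image, default_config(seed = 3))
  expect_equal(res$status, "ok")
  expect_equal(res$cup$loop_used, 1L)
  expect_equal(nrow(res$log), 1L)
  roi <- res$disc$roi
  disc_roi <- fundusCDR:::roi_crop(res$disc$mask, roi)
  expect_false(fundusCDR:::touches_disc_boundary(res$cup$mask, disc_roi))
})

test_that("cups touching the disc boundary on every loop give success = FALSE", {
  fx <- gradient_roi()
  # disc offset sideways so the bright blob straddles its boundary
  offset_disc <- test_circle(128, c(63.5, 20), 45)
  cfg <- cup_config(scale_area_floor = FALSE, area_floor = 100, seed = 5)
  res <- segment_cup(fx$img, offset_disc, fx$vessels, cfg)
  expect_false(res$success)
  expect_equal(sum(res$mask), 0)
  expect_true(all(res$log$touches))
  expect_equal(res$log$loop, 1:4)
})
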