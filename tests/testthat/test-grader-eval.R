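test_that("sample SD reproduces the protocol's printed per-image examples", {
  # six-grader HCDR set printing as 0.06
  expect_equal(round(sample_sd(c(0.54, 0.51, 0.49, 0.54, 0.43, 0.40)), 3), 0.058)
  # six-grader VCDR set printing as 0.03
  expect_equal(round(sample_sd(c(0.46, 0.52, 0.54, 0.50, 0.54, 0.48)), 3), 0.033)
  expect_equal(sample_sd(c(0.5, 0.5, 0.5)), 0)
  expect_error(sample_sd(0.5), "at least 2")
})

test_that("centroid SD is the Euclidean norm of per-coordinate sample SDs", {
  pts <- matrix(c(10, 10, 10, 10, 1, 2, 3, 4), ncol = 2)
  expect_equal(centroid_sd(pts), sd(1:4))  # one axis degenerate
  expect_equal(centroid_sd(matrix(5, 4, 2)), 0)
  set.seed(13)
  p6 <- matrix(rnorm(12, 100, 7), ncol = 2)
  oracle <- sqrt(sum((p6[, 1] - mean(p6[, 1]))^2) / 5 +
                 sum((p6[, 2] - mean(p6[, 2]))^2) / 5)
  expect_equal(centroid_sd(p6), oracle, tolerance = 1e-12)
  expect_error(centroid_sd(matrix(1, 1, 2)), "at least 2")
})

test_that("mean-SD thresholds average per-image spreads; CDR override is exact", {
  tbl <- one_image_table()
  thr0 <- sd_thresholds(tbl, override_cdr = NULL)
  expect_true(all(unlist(thr0) == 0))
  thr <- sd_thresholds(tbl)
  expect_identical(thr$hcdr, 0.075)
  expect_identical(thr$vcdr, 0.075)
  # known jitter: area threshold within 15% of the analytic jitter SD
  sim <- simulate_markings(flat_truth(300), grader_sim_spec(seed = 5))
  thr2 <- sd_thresholds(sim$markings, override_cdr = NULL)
  analytic <- 7800 * sqrt((exp(0.05^2) - 1) * exp(0.05^2))
  expect_lte(abs(thr2$disc_area - analytic) / analytic, 0.15)
})

test_that("outlier detection flags the displaced grader and stops at the threshold", {
  expect_equal(detect_outliers(c(0.5, 0.51, 0.49, 0.5, 0.5, 0.52), 0.075),
               character(0))
  v <- c(0.5, 0.5, 0.5, 0.5, 0.5, 0.9)
  expect_equal(detect_outliers(v, 0.075), "6")
  # never empties the set below 3 remaining values
  wild <- c(0, 10, 20, 30, 40, 50)
  fl <- detect_outliers(wild, 0.001)
  expect_lte(length(fl), 3)
  expect_identical(fl, detect_outliers(wild, 0.001))  # deterministic
  expect_error(detect_outliers(c(1, 2), 0.1), "at least 3")
})

test_that("image elimination follows the three outlier-count rules", {
  thr <- tight_thresholds(10)
  # >= 3 outliers on one parameter -> eliminated
  t1 <- one_image_table(list(
    list(grader = "1", col = "disc_area", value = 9000),
    list(grader = "2", col = "disc_area", value = 7000),
    list(grader = "3", col = "disc_area", value = 9500)))
  ev1 <- evaluate_entity(t1, "4", analysis_params("hcdr"), thr)
  expect_true(ev1$eliminated)
  # 3 outliers on distinct parameters -> kept
  t2 <- one_image_table(list(
    list(grader = "1", col = "disc_centroid_row", value = 200),
    list(grader = "2", col = "cup_area", value = 4000),
    list(grader = "3", col = "hcdr", value = 0.95)))
  ev2 <- evaluate_entity(t2, "4", analysis_params("hcdr"), thr)
  expect_false(ev2$eliminated)
  expect_true(ev2$tested)
  # 4 outliers with 2 sharing a parameter -> eliminated
  t3 <- one_image_table(list(
    list(grader = "1", col = "disc_area", value = 9000),
    list(grader = "2", col = "disc_area", value = 7000),
    list(grader = "3", col = "cup_area", value = 4000),
    list(grader = "5", col = "hcdr", value = 0.95)))
  ev3 <- evaluate_entity(t3, "4", analysis_params("hcdr"), thr)
  expect_true(ev3$eliminated)
})

test_that("entities are accurate iff unflagged; the algorithm joins as a seventh marking", {
  thr <- tight_thresholds(10)
  tbl <- one_image_table(list(list(grader = "6", col = "hcdr", value = 0.9)))
  ev6 <- evaluate_entity(tbl, "6", analysis_params("hcdr"), thr)
  expect_true(ev6$flagged); expect_false(ev6$accurate)
  ev1 <- evaluate_entity(tbl, "1", analysis_params("hcdr"), thr)
  expect_true(ev1$accurate)
  # algorithm far off -> flagged under its own evaluation
  rp <- region_params(8000, c(100, 100), 2500, c(100, 100), 0.95, 0.5)
  tba <- append_algorithm_markings(one_image_table(), "img1", list(rp))
  eva <- evaluate_entity(tba, "algorithm", analysis_params("hcdr"), thr)
  expect_true(eva$flagged)
  expect_error(evaluate_entity(tbl, "algorithm", analysis_params("hcdr"), thr),
               "not present")
})

test_that("accuracy percentages are truncated to one decimal", {
  expect_equal(accuracy_percentage(256, 343), 74.6)
  expect_equal(accuracy_percentage(222, 299), 74.2)
  expect_equal(accuracy_percentage(244, 315), 77.4)  # half-up would say 77.5
  expect_equal(accuracy_percentage(148, 194), 76.2)  # half-up would say 76.3
  expect_equal(accuracy_percentage(28, 54), 51.8)    # half-up would say 51.9
  expect_equal(fundusCDR:::round_half_up(0.25, 1), 0.3)
})

test_that("identical graders score 100% everywhere and agreement equals the diagonal", {
  tbl <- do.call(rbind, lapply(sprintf("im%02d", 1:5), function(id) {
    t <- one_image_table(); t$image_id <- id; t
  }))
  thr <- tight_thresholds(10)
  acc <- accuracy_table(tbl, thr, "final")
  expect_true(all(acc["percentage", ] == 100))
  expect_true(all(acc["tested", ] == 5))
  agr <- agreement_matrix(tbl, thr, "final")
  expect_true(all(agr == 5))
})

test_that("agreement matrix is symmetric and matches a brute-force recount", {
  sim <- simulate_markings(flat_truth(40),
                           grader_sim_spec(outlier_rate = 0.1,
                                           outlier_scale = 8, seed = 11))
  thr <- sd_thresholds(simulate_markings(flat_truth(40),
                                         grader_sim_spec(seed = 99))$markings,
                       override_cdr = 0.075)
  agr <- agreement_matrix(sim$markings, thr, "hcdr")
  expect_identical(agr, t(agr))
  expect_true(all(diag(agr) == 40))
  # independent recount from scratch for the pair ("1", "2")
  params <- analysis_params("hcdr")
  ids <- sort(unique(sim$markings$image_id))
  count <- 0
  for (id in ids) {
    rows <- sim$markings[sim$markings$image_id == id, ]
    rows <- rows[order(as.integer(rows$grader_id)), ]
    flags <- lapply(params, function(p)
      detect_outliers(fundusCDR:::param_values(rows, p), thr[[p]],
                      ids = rows$grader_id))
    counts <- lengths(flags)
    elim <- max(counts) >= 3 || (sum(counts) >= 4 && max(counts) >= 2)
    hit <- !elim && !any(vapply(flags, function(f) any(c("1", "2") %in% f),
                                logical(1)))
    count <- count + hit
  }
  expect_equal(agr["1", "2"], count)
  # off-diagonal entries never exceed either entity's tested count
  acc <- accuracy_table(sim$markings, thr, "hcdr")
  for (a in rownames(agr)) for (b in colnames(agr)) if (a != b)
    expect_lte(agr[a, b], min(acc["tested", a], acc["tested", b]))
})

test_that("with zero injected outliers and generous thresholds nothing is eliminated", {
  sim <- simulate_markings(flat_truth(60), grader_sim_spec(seed = 21))
  thr <- tight_thresholds(1e6)
  acc <- accuracy_table(sim$markings, thr, "final")
  expect_true(all(acc["percentage", ] == 100))
  expect_true(all(acc["removed", ] == 0))
})

test_that("injected outliers are recovered with high sensitivity", {
  clean <- simulate_markings(flat_truth(150), grader_sim_spec(seed = 31))
  thr <- sd_thresholds(clean$markings, override_cdr = 0.075)
  sim <- simulate_markings(flat_truth(150),
                           grader_sim_spec(outlier_rate = 0.1,
                                           outlier_scale = 10, seed = 32))
  det <- 0
  for (i in seq_len(nrow(sim$outliers))) {
    o <- sim$outliers[i, ]
    rows <- sim$markings[sim$markings$image_id == o$image_id, ]
    rows <- rows[order(as.integer(rows$grader_id)), ]
    fl <- detect_outliers(fundusCDR:::param_values(rows, o$param),
                          thr[[o$param]], ids = rows$grader_id)
    det <- det + (o$grader_id %in% fl)
  }
  expect_gte(det / nrow(sim$outliers), 0.9)
})
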