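# Shared fixtures. All phantoms are generated in code at test time.

# Phantom with cup-to-disc ratios drawn reproducibly from the suite seed,
# mirroring the study-suite construction used in scripts/acceptance.R.
suite_phantom <- function(seed, noise_sigma = 8, ...) {
  cdr <- withr::with_seed(fundusCDR:::sub_seed(seed, 77),
                          stats::runif(2, 0.35, 0.7))
  generate_phantom(phantom_spec(seed = seed, cdr_h = cdr[1], cdr_v = cdr[2],
                                noise_sigma = noise_sigma, ...))
}

# Filled circle helper in test frame.
test_circle <- function(n, center, radius) {
  r <- matrix(0:(n - 1), n, n)
  c_ <- matrix(0:(n - 1), n, n, byrow = TRUE)
  (r - center[1])^2 + (c_ - center[2])^2 <= radius^2
}

# A flat truth table for marking simulations.
flat_truth <- function(n_images, hcdr = 0.55, vcdr = 0.55) {
  data.frame(image_id = sprintf("im%03d", seq_len(n_images)),
             disc_area = 7800, disc_centroid_row = 256,
             disc_centroid_col = 280, cup_area = 2300,
             cup_centroid_row = 256, cup_centroid_col = 280,
             hcdr = hcdr, vcdr = vcdr, stringsAsFactors = FALSE)
}

# A one-image six-grader marking table built from per-grader parameter
# offsets; start from identical baseline rows and displace selected entries.
one_image_table <- function(displace = list()) {
  tbl <- do.call(rbind, lapply(1:6, function(g)
    data.frame(image_id = "img1", grader_id = as.character(g),
               disc_area = 8000, disc_centroid_row = 100,
               disc_centroid_col = 100, cup_area = 2500,
               cup_centroid_row = 100, cup_centroid_col = 100,
               hcdr = 0.5, vcdr = 0.5, stringsAsFactors = FALSE)))
  for (d in displace) tbl[tbl$grader_id == d$grader, d$col] <- d$value
  tbl
}

tight_thresholds <- function(value = 1e-6) {
  thr <- as.list(rep(value, 6))
  names(thr) <- fundusCDR:::param_groups
  thr$hcdr <- 0.075
  thr$vcdr <- 0.075
  structure(thr, class = "sd_thresholds")
}
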