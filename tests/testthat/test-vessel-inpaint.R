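test_that("vessel extraction: constant image gives an empty binary mask of image size", {
  img <- fundus_image(array(120L, c(100, 120, 3)))
  mask <- extract_vessels(img)
  expect_type(mask, "logical")
  expect_equal(dim(mask), c(100, 120))
  expect_equal(sum(mask), 0)
})

test_that("vessel extraction recovers phantom vessels (Dice >= 0.6, noiseless)", {
  ph <- generate_phantom(phantom_spec(seed = 3, n_vessels = 3, noise_sigma = 0))
  mask <- extract_vessels(ph$image)
  expect_gte(dice(mask, ph$vessels), 0.6)
})

test_that("vessel extraction rejects oversized structuring elements", {
  img <- fundus_image(array(120L, c(100, 100, 3)))
  expect_error(extract_vessels(img, vessel_params(radius = 60)), "radius")
})

test_that("vessel extraction is translation-equivariant on interior pixels", {
  ph <- generate_phantom(phantom_spec(seed = 9, n_vessels = 3, noise_sigma = 0))
  px <- ph$image$pixels
  dr <- 5L; dc <- 7L
  shifted <- px
  shifted[] <- 0L
  shifted[(1 + dr):512, (1 + dc):512, ] <- px[1:(512 - dr), 1:(512 - dc), ]
  # fixed threshold rule decouples the test from global-histogram effects of
  # the zero-padded border strip
  vp <- vessel_params(threshold_rule = "fixed", fixed_threshold = 50)
  m1 <- extract_vessels(ph$image, vp)
  m2 <- extract_vessels(fundus_image(shifted), vp)
  # compare away from all borders (structuring-element halo excluded)
  core <- 60:440
  agree <- mean(m1[core, core] == m2[core + dr, core + dc])
  expect_gte(agree, 0.99)
})

test_that("inpainting with an empty mask is the identity", {
  set.seed(2)
  img <- fundus_image(array(sample(0:255, 64 * 64 * 3, TRUE), c(64, 64, 3)))
  out <- inpaint(img, matrix(FALSE, 64, 64))
  expect_identical(out$pixels, img$pixels)
})

test_that("a single masked pixel in a constant region converges to that value", {
  img <- fundus_image(array(137L, c(64, 64, 3)))
  mask <- matrix(FALSE, 64, 64); mask[30, 30] <- TRUE
  out <- inpaint(img, mask)
  expect_equal(out$pixels[30, 30, 1], 137L)
})

test_that("inpainting a 5x5 hole matches the direct diffusion fixed point within 2 gray levels", {
  # oracle: solve the linear fixed-point system x = K x directly on the hole
  set.seed(8)
  base <- matrix(rep(seq(10, 240, length.out = 40), each = 40), 40, 40)
  base <- base + matrix(rnorm(1600, 0, 3), 40, 40)
  base <- pmin(pmax(base, 0), 255)
  mask <- matrix(FALSE, 40, 40); mask[18:22, 18:22] <- TRUE
  hole <- which(mask)
  w8 <- c(0.0625, 0.1875, 0.0625, 0.1875, 0.1875, 0.0625, 0.1875, 0.0625)
  off <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  A <- diag(length(hole))
  b <- numeric(length(hole))
  hr <- (hole - 1) %% 40 + 1; hc <- (hole - 1) %/% 40 + 1
  for (i in seq_along(hole)) {
    for (k in 1:8) {
      nb <- (hc[i] + off[k, 2] - 1) * 40 + hr[i] + off[k, 1]
      j <- match(nb, hole)
      if (is.na(j)) b[i] <- b[i] + w8[k] * base[nb]
      else A[i, j] <- A[i, j] - w8[k]
    }
  }
  oracle <- solve(A, b)
  got <- fundusCDR:::inpaint_channel(base, mask, iterations = 5000, tol = 1e-6)
  expect_lte(max(abs(got[hole] - oracle)), 2)
})

test_that("inpainting never changes unmasked pixels and obeys the maximum principle", {
  set.seed(5)
  base <- matrix(runif(64 * 64, 50, 200), 64, 64)
  mask <- matrix(FALSE, 64, 64); mask[20:26, 31:37] <- TRUE
  out <- fundusCDR:::inpaint_channel(base, mask, iterations = 2000, tol = 1e-4)
  expect_identical(out[!mask], base[!mask])
  ring <- fundusCDR:::dilate8(mask) & !mask
  expect_gte(min(out[mask]), min(base[ring]) - 1e-6)
  expect_lte(max(out[mask]), max(base[ring]) + 1e-6)
})

test_that("inpainting an all-true mask is an error", {
  img <- fundus_image(array(10L, c(64, 64, 3)))
  expect_error(inpaint(img, matrix(TRUE, 64, 64)), "boundary")
})
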