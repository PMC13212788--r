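test_that("confidence weights are exact at certainty and minimal at p = 0.5", {
  expect_identical(confidence_weights(0), 1)
  expect_identical(confidence_weights(1), 1)
  expect_equal(confidence_weights(0.5), 0.2 / 0.45, tolerance = 1e-13)
  p <- seq(0, 1, by = 0.01)
  w <- confidence_weights(p)
  expect_true(all(w >= 0.2 / 0.45 - 1e-12 & w <= 1))
  # symmetry about 0.5
  expect_equal(w, rev(w), tolerance = 1e-12)
  expect_error(confidence_weights(0.5, alpha = 0), "positive")
  expect_error(confidence_weights(1.2), "\\[0, 1\\]")
})

test_that("the autocorrelation model recovers an exponential correlation length", {
  set.seed(41)
  # smooth latent field with exponential-like decay, thresholded to labels
  n <- 48L
  L_true <- 6  # pixels
  base <- matrix(rnorm((n + 20)^2), n + 20)
  k <- outer(-10:10, -10:10, function(a, b) exp(-sqrt(a^2 + b^2) / L_true))
  sm <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    sm[i, j] <- sum(base[i:(i + 20), j:(j + 20)] * k)
  }
  labels <- lapply(1:3, function(s) (sm > quantile(sm, 0.8)) * 1L)
  slices <- make_slices(labels, slice_index = c(1L, 3L, 5L),
                        pixel_spacing_mm = 1)
  model <- estimate_slice_autocorrelation(slices)
  expect_true(model$has_correlation)
  expect_gt(model$length_mm, 1)
  expect_lt(model$length_mm, 30)
  expect_equal(model$prior, 0.2, tolerance = 0.01)
  # empirical correlation starts at 1 and decays
  expect_equal(model$rho[model$lags_mm == 0], 1, tolerance = 1e-9)
  expect_lt(model$rho[which.max(model$lags_mm)], 0.5)
})

test_that("single-class slices fall back to a prior-only model", {
  labels <- lapply(1:2, function(s) matrix(0L, 8, 8))
  slices <- make_slices(labels, slice_index = c(1L, 3L))
  expect_warning(model <- estimate_slice_autocorrelation(slices), "floor")
  expect_false(model$has_correlation)
  expect_equal(model$prior, 0.01)
  p <- wiener_interpolate(slices, model, c(5L, 8L, 8L))
  expect_equal(p[2, , ], matrix(0.01, 8, 8))
  expect_equal(p[1, , ], matrix(0, 8, 8))  # observed slices stay exact
})

test_that("kriging reproduces slice labels and decays to the prior far away", {
  set.seed(42)
  labels <- lapply(1:2, function(s)
    (matrix(runif(12 * 12), 12) > 0.7) * 1L)
  slices <- make_slices(labels, slice_index = c(2L, 4L), pixel_spacing_mm = 2)
  model <- structure(list(length_mm = 4, prior = 0.3, has_correlation = TRUE),
                     class = "autocorrelation_model")
  p <- wiener_interpolate(slices, model, c(40L, 12L, 12L))
  expect_equal(p[2, , ], labels[[1]] * 1, tolerance = 1e-9)
  expect_equal(p[4, , ], labels[[2]] * 1, tolerance = 1e-9)
  # 36 voxels = 72 mm = 18 correlation lengths past the last slice
  expect_lt(max(abs(p[40, , ] - 0.3)), 0.01)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("the axial-only stencil matches the two-point simple-kriging closed form", {
  labels <- list(matrix(1, 3, 3), matrix(0, 3, 3))
  slices <- make_slices(labels, slice_index = c(1L, 5L), pixel_spacing_mm = 2)
  L <- 5; m <- 0.25
  model <- structure(list(length_mm = L, prior = m, has_correlation = TRUE),
                     class = "autocorrelation_model")
  p <- wiener_interpolate(slices, model, c(5L, 3L, 3L), in_plane_radius_mm = 0)
  # midpoint layer 3: distances 4 mm to both slices, slice gap 8 mm
  r1 <- exp(-4 / L); r12 <- exp(-8 / L)
  w <- solve(matrix(c(1, r12, r12, 1), 2), c(r1, r1))
  expected <- m + w[1] * (1 - m) + w[2] * (0 - m)
  expect_equal(p[3, 2, 2], expected, tolerance = 1e-12)
})

test_that("build_reference assembles labels and weights consistent with p", {
  st <- small_study()
  ref <- build_reference(st)
  expect_s3_class(ref, "reference_volume")
  expect_identical(ref$label, binarize_reference(ref$p))
  expect_equal(ref$weight, confidence_weights(ref$p), tolerance = 1e-12)
  # the reference broadly agrees with the generating truth inside the gland
  inpro <- st$prostate_mask
  agree <- mean((ref$p[inpro] >= 0.5) == (st$lesion_mask[inpro]))
  expect_gt(agree, 0.85)
})
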