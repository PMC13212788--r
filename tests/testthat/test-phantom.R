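test_that("phantom geometry is anatomically consistent", {
  st <- small_study()
  expect_s3_class(st, "phantom_study")
  # zones partition the gland; lesions sit inside it
  expect_true(all(st$pz_mask | st$tz_mask | !st$prostate_mask))
  expect_false(any(st$pz_mask & st$tz_mask))
  expect_true(all(st$prostate_mask[st$lesion_mask]))
  # achieved prevalence honours the configured tolerance
  prev <- sum(st$lesion_mask) / sum(st$prostate_mask)
  expect_lt(abs(prev - 0.07) / 0.07, 0.2 + 1e-12)
  expect_true(st$clinical$volume_cc > 0)
  expect_true(st$clinical$psa_ng_ml > 0)
})

test_that("generation is deterministic under the seed", {
  a <- generate_phantom_study(small_phantom_config(seed = 77L))
  b <- generate_phantom_study(small_phantom_config(seed = 77L))
  expect_identical(a$lesion_mask, b$lesion_mask)
  expect_identical(a$ceus_loop$data, b$ceus_loop$data)
  expect_identical(a$truth$sws, b$truth$sws)
  d <- generate_phantom_study(small_phantom_config(seed = 78L))
  expect_false(identical(a$lesion_mask, d$lesion_mask))
})

test_that("infeasible prevalence/lesion-size demands fail fast", {
  cfg <- phantom_config(grid_shape = c(16L, 16L, 16L), n_lesions = 4L,
                        target_prevalence = 0.5, seed = 1L)
  expect_error(generate_phantom_study(cfg),
               "prevalence|radii|place a lesion")
})

test_that("the CEUS loop carries a physiological contrast passage", {
  st <- small_study()
  tv <- st$ceus_loop
  expect_s3_class(tv, "tic_volume")
  idx <- which(st$prostate_mask)
  Y <- matrix(tv$data, ncol = length(tv$time_s))[idx, , drop = FALSE]
  # intensity rises from baseline to a peak and partially washes out
  m <- colMeans(Y)
  pk <- which.max(m)
  expect_gt(pk, 3)
  expect_lt(pk, length(m))
  expect_gt(max(m), 3 * m[1])
})

test_that("histology slices subsample the truth at the configured spacing", {
  st <- small_study()
  hs <- st$histology_slices
  gap <- unique(diff(hs$slice_index))
  expect_length(gap, 1L)
  expect_equal(gap * st$grid$voxel_size_mm, hs$spacing_mm)
  for (s in seq_along(hs$slice_index)) {
    expect_identical(hs$labels[[s]] > 0,
                     st$lesion_mask[hs$slice_index[s], , ])
  }
})

test_that("separable and default configurations share the grid contract", {
  c1 <- phantom_config(seed = 5L)
  c2 <- phantom_config_separable(seed = 5L)
  expect_identical(c1$grid_shape, c2$grid_shape)
  expect_identical(c1$target_prevalence, c2$target_prevalence)
  # separability widens the malignant/benign parameter gap
  expect_gt(min(c2$hemodynamics_malignant$kappa),
            max(c2$hemodynamics_benign$kappa))
  expect_lt(max(c2$hemodynamics_malignant$mu),
            min(c2$hemodynamics_benign$mu))
  expect_gt(min(c2$stiffness_malignant), max(c2$stiffness_benign))
})
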