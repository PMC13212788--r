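test_that("feature extraction covers the gland with the full channel set", {
  p <- small_patient()
  expect_s3_class(p, "patient_features")
  expected <- c("kappa", "mu", "t0", "peak", "wash_in", "cd_vmag", "cd_d",
                "sa_corr", "sa_coh", "sa_mi", "ve_h", "ve_hcond",
                "swe_sws", "swe_e", "swe_quality")
  expect_setequal(names(p$features), expected)
  inpro <- p$prostate_mask
  for (nm in expected) {
    cov <- mean(is.finite(p$features[[nm]][inpro]))
    expect_gt(cov, 0.5, label = sprintf("coverage of %s", nm))
  }
  expect_setequal(names(p$location), c("loc_pz", "loc_dist", "loc_elev"))
  expect_setequal(names(p$clinical), c("volume_cc", "psa_density"))
  expect_true(all(is.finite(p$clinical)))
})

test_that("extracted hemodynamics separate lesion from benign tissue", {
  p <- small_patient()
  st <- small_study()
  les <- st$lesion_mask
  ben <- st$prostate_mask & !les
  # malignant tissue has higher dispersion kappa and shorter transit mu
  expect_gt(median(p$features$kappa[les], na.rm = TRUE),
            median(p$features$kappa[ben], na.rm = TRUE))
  expect_lt(median(p$features$mu[les], na.rm = TRUE),
            median(p$features$mu[ben], na.rm = TRUE))
  expect_gt(median(p$features$swe_sws[les], na.rm = TRUE),
            median(p$features$swe_sws[ben], na.rm = TRUE))
})

test_that("standardisation is leakage-safe and invertible", {
  cohort <- small_cohort()
  stats <- compute_feature_stats(cohort, scope_ids = 1:2)
  expect_s3_class(stats, "feature_stats")
  expect_identical(attr(stats, "stats_scope"), "train_folds_only")
  # scope restriction changes the statistics
  stats_all <- compute_feature_stats(cohort)
  expect_false(isTRUE(all.equal(stats$mean, stats_all$mean)))
  # standardized kappa over the scope has mean ~0 and sd ~1
  pooled <- unlist(lapply(cohort[1:2], function(p)
    p$features$kappa[p$prostate_mask]))
  z <- (pooled - stats$mean[stats$feature == "kappa"]) /
    stats$sd[stats$feature == "kappa"]
  expect_lt(abs(mean(z, na.rm = TRUE)), 1e-10)
  expect_equal(sd(z, na.rm = TRUE), 1, tolerance = 1e-10)
  # branch stacks impute missing values to zero after z-scoring
  bs <- branch_stack(cohort[[1]], c("kappa", "swe_sws"),
                     c("loc_pz", "loc_dist"), stats)
  expect_identical(dim(bs), as.integer(c(prod(cohort[[1]]$grid$shape), 4L)))
  expect_true(all(is.finite(bs)))
})
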