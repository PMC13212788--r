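test_that("mldrw_curve integrates to its area parameter and peaks past t0", {
  t <- seq(0, 120, by = 0.05)
  fit <- structure(list(kappa = 2, mu = 20, t0 = 5, auc = 7),
                   class = "mldrw_fit")
  y <- mldrw_curve(fit, t)
  expect_true(all(y[t <= 5] == 0))
  area <- sum((y[-1] + y[-length(y)]) / 2 * diff(t))
  expect_lt(abs(area - 7) / 7, 1e-3)
  expect_gt(t[which.max(y)], 5)
  expect_equal(t[which.max(y)], mldrw_peak_time(fit), tolerance = 0.06)
})

test_that("matrix fitting recovers noise-free parameters", {
  set.seed(4)
  n <- 40L
  theta <- cbind(kappa = runif(n, 0.5, 8), mu = runif(n, 10, 40),
                 t0 = runif(n, 1, 12), auc = runif(n, 0.5, 5))
  t <- seq(0, 90, by = 0.5)
  Y <- mldrw_truth_curves(theta, t)
  fit <- fit_mldrw_matrix(Y, t)
  expect_true(all(fit$converged))
  rel <- abs(fit$theta - theta) / abs(theta)
  expect_lt(max(rel), 1e-2)
  expect_true(all(fit$r2 > 0.999))
})

test_that("fitting is invariant to intensity scaling except in the area", {
  set.seed(5)
  theta <- cbind(kappa = 2.5, mu = 22, t0 = 4, auc = 1.5)
  t <- seq(0, 90, by = 0.5)
  Y <- mldrw_truth_curves(theta, t)
  f1 <- fit_mldrw_matrix(Y, t)
  f2 <- fit_mldrw_matrix(10 * Y, t)
  expect_equal(f2$theta[, "auc"], 10 * f1$theta[, "auc"], tolerance = 1e-5)
  expect_equal(f2$theta[, c("kappa", "mu", "t0")],
               f1$theta[, c("kappa", "mu", "t0")], tolerance = 1e-5)
})

test_that("flat and non-finite curves are flagged, not fitted", {
  t <- seq(0, 60, by = 1)
  Y <- rbind(rep(0, length(t)), c(NA, seq_len(length(t) - 1)))
  fit <- fit_mldrw_matrix(Y, t)
  expect_false(any(fit$converged))
  expect_true(all(is.na(fit$theta[1, ])))
})

test_that("temporal feature derivation reports peak and wash-in time", {
  t <- seq(0, 90, by = 0.5)
  theta <- cbind(kappa = c(2, 4), mu = c(20, 30), t0 = c(3, 6),
                 auc = c(1, 2))
  Y <- mldrw_truth_curves(theta, t)
  tv <- tic_volume(array(Y, dim = c(2, 1, 1, length(t))), t)
  fits <- fit_mldrw_volume(tv)
  fx <- derive_temporal_features(fits)
  expect_setequal(names(fx), c("kappa", "mu", "t0", "peak", "wash_in"))
  expect_true(all(fx$wash_in > 0, na.rm = TRUE))
  # the reported peak value matches the sampled curve maximum (the 0.5 s
  # sampling grid slightly undershoots the analytic peak)
  expect_equal(as.vector(fx$peak), apply(Y, 1, max), tolerance = 1e-2)
  # non-converged voxels are missing everywhere
  fits$converged[2] <- FALSE
  fx2 <- derive_temporal_features(fits)
  expect_true(all(is.na(vapply(fx2, function(a) a[2], 1))))
})

test_that("intensity linearisation inverts log compression", {
  x <- array(runif(3 * 3 * 2 * 5, 1e-4, 1), dim = c(3, 3, 2, 5))
  db <- compress_intensity(x)
  tv <- linearize_intensity(db, dynamic_range_db = 60)
  expect_equal(tv$data, x, tolerance = 1e-12)
  expect_true(all(tv$mask))
  # samples below the dynamic-range floor invalidate the voxel
  db[1, 1, 1, 1] <- -80
  expect_false(linearize_intensity(db, dynamic_range_db = 60)$mask[1, 1, 1])
})
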