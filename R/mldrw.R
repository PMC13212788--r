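# Temporal contrast-ultrasound dispersion imaging (1D CUDI): linearization of
# log-compressed intensities, the modified local-density-random-walk (mLDRW)
# indicator-dilution model, per-voxel nonlinear least-squares fitting, and the
# derived temporal feature maps.

#' Construct a time-intensity-curve volume
#'
#' A `tic_volume` holds a 4D array of linear (concentration-proportional)
#' contrast intensities on a regular voxel grid with a uniform time axis.
#'
#' @param data 4D numeric array `(x, y, z, t)` of linear intensities (a.u.).
#' @param time_s Numeric vector of frame times (s); strictly increasing with a
#'   uniform step.
#' @param mask Logical 3D array marking voxels with valid TICs. Defaults to
#'   voxels whose TIC is finite everywhere.
#' @param voxel_size_mm Isotropic voxel spacing in mm.
#' @return An object of class `tic_volume`.
#' @export
tic_volume <- function(data, time_s, mask = NULL, voxel_size_mm = 1) {
  stopifnot(length(dim(data)) == 4L, length(time_s) == dim(data)[4])
  dt <- diff(time_s)
  if (any(dt <= 0)) stop("time axis must be strictly increasing")
  if (length(dt) > 1 && max(abs(dt - dt[1])) > 1e-6 * dt[1]) {
    stop("time axis must have a uniform step")
  }
  d <- dim(data)[1:3]
  if (is.null(mask)) {
    nt <- dim(data)[4]
    mask <- array(.rowSums(!is.finite(data), prod(d), nt) == 0L, d)
  }
  stopifnot(all(dim(mask) == d))
  structure(
    list(data = data, time_s = as.numeric(time_s), mask = mask,
         voxel_size_mm = voxel_size_mm),
    class = "tic_volume"
  )
}

#' @export
print.tic_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("tic_volume: %d x %d x %d voxels, %d frames (dt = %.3g s), %d masked voxels\n",
              d[1], d[2], d[3], d[4], diff(x$time_s[1:2]), sum(x$mask)))
  invisible(x)
}

#' Linearize log-compressed display intensities
#'
#' Inverts the scanner's logarithmic compression so that intensities become
#' proportional to contrast-agent concentration: `linear = 10^(dB / 10)`.
#' Non-finite samples and voxels darker than the dynamic range floor are
#' masked out.
#'
#' @param raw_db_volume 4D array of log-compressed intensities (dB).
#' @param dynamic_range_db Display dynamic range; samples below
#'   `-dynamic_range_db` are considered clipped.
#' @param time_s Frame times (s).
#' @param voxel_size_mm Voxel spacing (mm).
#' @return A [tic_volume] with linear intensities.
#' @export
linearize_intensity <- function(raw_db_volume, dynamic_range_db = 60,
                                time_s = seq_len(dim(raw_db_volume)[4]) - 1,
                                voxel_size_mm = 1) {
  stopifnot(length(dim(raw_db_volume)) == 4L, dynamic_range_db > 0)
  lin <- 10^(raw_db_volume / 10)
  bad <- !is.finite(raw_db_volume)
  lin[bad] <- NA_real_
  d <- dim(raw_db_volume)
  viol <- bad | raw_db_volume < -dynamic_range_db
  valid <- array(.rowSums(viol, prod(d[1:3]), d[4]) == 0L, d[1:3])
  tic_volume(lin, time_s, mask = valid, voxel_size_mm = voxel_size_mm)
}

#' Log-compress linear intensities (inverse of [linearize_intensity])
#'
#' @param linear_volume Array of linear intensities (> 0).
#' @return Array of log-compressed intensities in dB.
#' @export
compress_intensity <- function(linear_volume) {
  10 * log10(linear_volume)
}

#' Evaluate the mLDRW indicator-dilution curve
#'
#' The modified local-density-random-walk model describes the bolus passage at
#' one location:
#' \deqn{C(t) = \mathrm{auc}\,\sqrt{\kappa / (2\pi (t - t_0))}\,
#'   \exp\{-\kappa (t - t_0 - \mu)^2 / (2 (t - t_0))\}, \quad t > t_0,}
#' and 0 otherwise. `kappa` (1/s) increases with local dispersion, `mu` (s) is
#' the mean transit time from the (theoretical) injection site, `t0` (s) the
#' injection-time offset and `auc` the area under the curve, to which the
#' curve integrates exactly.
#'
#' @param fit List (or `mldrw_fit`) with elements `kappa`, `mu`, `t0`, `auc`.
#' @param t Numeric vector of times (s).
#' @return Numeric vector of intensities.
#' @export
mldrw_curve <- function(fit, t) {
  kappa <- fit$kappa; mu <- fit$mu; t0 <- fit$t0; auc <- fit$auc
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be positive")
  if (!is.finite(mu) || mu <= 0) stop("mu must be positive")
  s <- t - t0
  out <- numeric(length(t))
  pos <- s > 0
  sp <- s[pos]
  out[pos] <- auc * sqrt(kappa / (2 * pi * sp)) * exp(-kappa * (sp - mu)^2 / (2 * sp))
  out
}

#' Analytic peak time of an mLDRW curve
#'
#' Setting the derivative of the curve to zero gives
#' `t_peak = t0 + (sqrt(1 + 4 kappa^2 mu^2) - 1) / (2 kappa)`, which tends to
#' `t0 + mu` for `kappa * mu >> 1`.
#'
#' @inheritParams mldrw_curve
#' @return Peak time (s).
#' @export
mldrw_peak_time <- function(fit) {
  fit$t0 + (sqrt(1 + 4 * fit$kappa^2 * fit$mu^2) - 1) / (2 * fit$kappa)
}

# --- vectorised model evaluation and Jacobian over a parameter matrix ---
# theta: n x 4 matrix (kappa, mu, t0, auc); t: length-m vector.
# Returns list(f = n x m, and if jac: J as list of four n x m matrices).
#' @keywords internal
mldrw_eval <- function(theta, t, jacobian = FALSE) {
  storage.mode(theta) <- "double"
  .Call(C_mldrw_eval, theta, as.numeric(t), isTRUE(jacobian))
}

# Moment-based initial values for a matrix of TICs (n x m).
#' @keywords internal
mldrw_init <- function(Y, t) {
  n <- nrow(Y); m <- length(t)
  peak <- Y[, 1]
  for (j in seq_len(m)[-1L]) peak <- pmax(peak, Y[, j])
  thresh <- 0.05 * peak
  above <- Y > thresh
  first_idx <- max.col(above, ties.method = "first")
  first_idx[!above[cbind(seq_len(n), first_idx)]] <- 1L
  dt <- t[2] - t[1]
  t0 <- pmax(t[first_idx] - dt, 0)
  Wpos <- pmax(Y, 0)
  w <- rowSums(Wpos)
  w[w <= 0] <- 1
  tbar <- as.vector(Wpos %*% t) / w
  tvar <- as.vector(Wpos %*% t^2) / w - tbar^2
  mu <- pmax(tbar - t0, dt)
  kappa <- mu / pmax(tvar, dt^2 / 4)
  auc <- as.vector((Wpos[, -1L, drop = FALSE] + Wpos[, -m, drop = FALSE]) %*%
                     (t[-1L] - t[-m])) / 2
  cbind(kappa = pmin(pmax(kappa, 1e-3), 50),
        mu = mu, t0 = t0, auc = pmax(auc, 1e-12))
}

#' Fit the mLDRW model to a matrix of TICs
#'
#' Vectorised bounded Levenberg-Marquardt over all curves simultaneously, with
#' analytic Jacobian and per-curve damping. Convergence requires the solver to
#' terminate on the step-size tolerance and the coefficient of determination
#' to exceed `r2_floor`.
#'
#' @param Y Numeric matrix `(n_curves, n_times)` of linear intensities.
#' @param time_s Frame times (s).
#' @param max_iter Maximum iterations (default 200).
#' @param tol Relative step-size convergence tolerance (default 1e-8).
#' @param r2_floor Minimum R-squared for a fit to count as converged.
#' @param lower,upper Parameter bounds, named vectors over
#'   `(kappa, mu, t0, auc)`.
#' @return A list with matrix `theta` (`kappa`, `mu`, `t0`, `auc`), vectors
#'   `r2` and `converged`.
#' @export
fit_mldrw_matrix <- function(Y, time_s, max_iter = 200L, tol = 1e-8,
                             r2_floor = 0.5,
                             lower = c(kappa = 1e-3, mu = 0.1, t0 = 0, auc = 0),
                             upper = c(kappa = 100, mu = Inf, t0 = Inf, auc = Inf)) {
  stopifnot(is.matrix(Y), ncol(Y) == length(time_s))
  n <- nrow(Y)
  t <- as.numeric(time_s)
  upper <- pmin(upper, c(kappa = Inf, mu = 4 * max(t), t0 = max(t), auc = Inf))

  active <- rowSums(abs(Y), na.rm = TRUE) > 0 & rowSums(!is.finite(Y)) == 0
  theta <- mldrw_init(Y, t)
  theta <- clamp_theta(theta, lower, upper)
  lambda <- rep(1e-2, n)
  m <- length(t)
  ev <- mldrw_eval(theta, t)
  sse <- .rowSums((ev$f - Y)^2, n, m)
  done <- !active
  stalled <- rep(FALSE, n)

  for (it in seq_len(max_iter)) {
    act <- which(!done)
    if (!length(act)) break
    th_a <- theta[act, , drop = FALSE]
    Y_a <- Y[act, , drop = FALSE]
    ev <- mldrw_eval(th_a, t, jacobian = TRUE)
    r <- Y_a - ev$f
    J <- ev$J
    # normal equations per curve: (J'J + lambda diag(J'J)) dtheta = J'r
    na <- length(act)
    # fused normal-equation reductions, ordered (11,21,31,41,22,32,42,33,43,44)
    ne <- .Call(C_mldrw_normal, J, r)
    K <- ne$K
    lam <- lambda[act]
    Kd <- K
    Kd[[1]] <- K[[1]] + lam * pmax(K[[1]], 1e-12)
    Kd[[5]] <- K[[5]] + lam * pmax(K[[5]], 1e-12)
    Kd[[8]] <- K[[8]] + lam * pmax(K[[8]], 1e-12)
    Kd[[10]] <- K[[10]] + lam * pmax(K[[10]], 1e-12)
    b <- ne$b
    sol <- batch_solve_sym4(Kd, b)
    cand <- clamp_theta(th_a + sol$x, lower, upper)
    ev_new <- mldrw_eval(cand, t)
    sse_new <- .rowSums((ev_new$f - Y_a)^2, na, m)
    improve <- sol$ok & is.finite(sse_new) & (sse_new <= sse[act])
    rel_step <- rowMaxs_abs((cand - th_a) / pmax(abs(th_a), 1e-6))
    conv_now <- improve & rel_step < tol
    if (any(improve)) {
      ai <- act[improve]
      theta[ai, ] <- cand[improve, , drop = FALSE]
      sse[ai] <- sse_new[improve]
      lambda[ai] <- pmax(lambda[ai] / 3, 1e-10)
    }
    ar <- act[!improve]
    lambda[ar] <- pmin(lambda[ar] * 8, 1e12)
    stalled_now <- !improve & lambda[act] >= 1e12
    done[act] <- done[act] | conv_now | stalled_now
    stalled[act] <- stalled[act] | stalled_now
  }

  ev <- mldrw_eval(theta, t)
  sse <- .rowSums((ev$f - Y)^2, n, m)
  sst <- .rowSums((Y - .rowMeans(Y, n, m))^2, n, m)
  r2 <- ifelse(sst > 0, 1 - sse / sst, -Inf)
  converged <- active & !stalled & is.finite(r2) & r2 >= r2_floor
  theta[!active, ] <- NA_real_
  list(theta = theta, r2 = r2, converged = converged)
}

#' @keywords internal
clamp_theta <- function(theta, lower, upper) {
  for (j in 1:4) theta[, j] <- pmin(pmax(theta[, j], lower[j]), upper[j])
  theta
}

#' @keywords internal
rowMaxs_abs <- function(m) {
  a <- abs(m)
  out <- a[, 1]
  for (j in seq_len(ncol(m))[-1L]) out <- pmax(out, a[, j])
  out
}

#' Fit the mLDRW model to one TIC
#'
#' Single-curve front end to [fit_mldrw_matrix].
#'
#' @param tic Numeric vector of linear intensities.
#' @param time_s Frame times (s); at least 20 samples spanning wash-in and part
#'   of wash-out.
#' @param ... Passed to [fit_mldrw_matrix].
#' @return An `mldrw_fit` list: `kappa`, `mu`, `t0`, `auc`, `r2`, `converged`.
#' @export
fit_mldrw <- function(tic, time_s, ...) {
  if (length(tic) < 20) warning("TIC has fewer than 20 samples; fit may be unstable")
  res <- fit_mldrw_matrix(matrix(tic, nrow = 1), time_s, ...)
  fit <- list(kappa = res$theta[1, 1], mu = res$theta[1, 2],
              t0 = res$theta[1, 3], auc = res$theta[1, 4],
              r2 = res$r2[1], converged = res$converged[1])
  class(fit) <- "mldrw_fit"
  fit
}

#' @export
print.mldrw_fit <- function(x, ...) {
  cat(sprintf("mldrw_fit: kappa=%.4g 1/s, mu=%.4g s, t0=%.4g s, auc=%.4g, r2=%.4f, converged=%s\n",
              x$kappa, x$mu, x$t0, x$auc, x$r2, x$converged))
  invisible(x)
}

#' Fit the mLDRW model at every masked voxel of a TIC volume
#'
#' @param ticvol A [tic_volume].
#' @param ... Passed to [fit_mldrw_matrix].
#' @return An `mldrw_fit_volume`: list of 3D parameter arrays (`kappa`, `mu`,
#'   `t0`, `auc`, `r2`), a logical `converged` array, plus the time axis.
#' @export
fit_mldrw_volume <- function(ticvol, ...) {
  stopifnot(inherits(ticvol, "tic_volume"))
  d <- dim(ticvol$data)[1:3]
  idx <- which(ticvol$mask)
  nt <- dim(ticvol$data)[4]
  Y <- matrix(ticvol$data, ncol = nt)[idx, , drop = FALSE]
  res <- fit_mldrw_matrix(Y, ticvol$time_s, ...)
  out <- list()
  for (j in seq_along(c("kappa", "mu", "t0", "auc"))) {
    a <- array(NA_real_, dim = d)
    a[idx] <- ifelse(res$converged, res$theta[, j], NA_real_)
    out[[c("kappa", "mu", "t0", "auc")[j]]] <- a
  }
  r2 <- array(NA_real_, dim = d); r2[idx] <- res$r2
  conv <- array(FALSE, dim = d); conv[idx] <- res$converged
  structure(list(kappa = out$kappa, mu = out$mu, t0 = out$t0, auc = out$auc,
                 r2 = r2, converged = conv, time_s = ticvol$time_s,
                 voxel_size_mm = ticvol$voxel_size_mm),
            class = "mldrw_fit_volume")
}

#' Derive temporal (1D CUDI) feature maps from per-voxel mLDRW fits
#'
#' Produces maps of `kappa`, `mu`, appearance time `t0`, fitted peak intensity
#' and wash-in time (time from 5\% to 95\% of the fitted peak on the rising
#' edge). Non-converged voxels are missing in every map.
#'
#' @param fits An `mldrw_fit_volume` from [fit_mldrw_volume].
#' @return Named list of 3D feature arrays.
#' @export
derive_temporal_features <- function(fits) {
  stopifnot(inherits(fits, "mldrw_fit_volume"))
  conv <- fits$converged & is.finite(fits$kappa)
  d <- dim(fits$kappa)
  idx <- which(conv)
  peak <- array(NA_real_, dim = d)
  wash_in <- array(NA_real_, dim = d)
  if (length(idx)) {
    kap <- fits$kappa[idx]; mu <- fits$mu[idx]; t0 <- fits$t0[idx]; auc <- fits$auc[idx]
    s_peak <- (sqrt(1 + 4 * kap^2 * mu^2) - 1) / (2 * kap)
    gpk <- sqrt(kap / (2 * pi * s_peak)) * exp(-kap * (s_peak - mu)^2 / (2 * s_peak))
    peak[idx] <- auc * gpk
    # rising-edge crossing times by bisection on s in (0, s_peak)
    wash_in[idx] <- rising_crossing(kap, mu, s_peak, 0.95) -
      rising_crossing(kap, mu, s_peak, 0.05)
  }
  list(kappa = mask_to(fits$kappa, conv), mu = mask_to(fits$mu, conv),
       t0 = mask_to(fits$t0, conv), peak = peak, wash_in = wash_in)
}

# s at which the normalised rising edge reaches `frac` of the peak value;
# vectorised bisection (the curve is monotone on (0, s_peak)).
#' @keywords internal
rising_crossing <- function(kappa, mu, s_peak, frac, iters = 60L) {
  gfun <- function(s) sqrt(kappa / (2 * pi * s)) * exp(-kappa * (s - mu)^2 / (2 * s))
  target <- frac * gfun(s_peak)
  lo <- rep(1e-9, length(kappa))
  hi <- s_peak
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    below <- gfun(mid) < target
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

#' @keywords internal
mask_to <- function(a, keep) {
  a[!keep] <- NA_real_
  a
}
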