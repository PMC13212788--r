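# Voxel-wise reference standard: an isotropic exponential autocorrelation
# model estimated on the sparse histology slices drives a simple-kriging
# (Wiener) interpolation of the binary lesion labels into a per-voxel csPCa
# probability volume, from which hard labels and confidence weights follow.

#' Estimate the isotropic label autocorrelation from histology slices
#'
#' Computes the empirical in-plane radial autocorrelation of the centred label
#' field (within the prostate cross-sections), pooled over slices, and fits a
#' monotone exponential model `rho(d) = exp(-d / length_mm)` by pair-count
#' weighted least squares. The model prior is the overall malignant fraction
#' within the prostate.
#'
#' @param slices A `histology_slices` object (binary `labels` and `prostate`
#'   images plus `pixel_spacing_mm`), or any list with those fields. `labels`
#'   images may also be continuous, in which case only the correlation part is
#'   meaningful.
#' @param max_lag_mm Largest lag entering the fit (default: half the image
#'   extent).
#' @param prior_floor Replacement prior when no malignant pixel exists
#'   (default 0.01, with a warning).
#' @return An `autocorrelation_model`: `length_mm`, `prior`, empirical
#'   `lags_mm`/`rho`, `has_correlation` (FALSE for single-class prior-only
#'   models) and `prior_floored`.
#' @export
estimate_slice_autocorrelation <- function(slices, max_lag_mm = NULL,
                                           prior_floor = 0.01) {
  h <- slices$pixel_spacing_mm
  stopifnot(is.numeric(h), length(slices$labels) >= 1L)
  masks <- slices$prostate
  if (is.null(masks)) masks <- lapply(slices$labels, function(l) array(TRUE, dim(l)))

  vals <- unlist(mapply(function(l, m) l[m], slices$labels, masks,
                        SIMPLIFY = FALSE))
  prior <- mean(vals)
  prior_floored <- FALSE
  if (!is.finite(prior) || prior <= 0) {
    warning("no malignant pixel on any slice: prior replaced by the floor")
    prior <- prior_floor
    prior_floored <- TRUE
  }
  single_class <- stats::var(vals) == 0 || prior_floored
  if (single_class) {
    return(structure(list(length_mm = NA_real_, prior = min(prior, 1),
                          lags_mm = numeric(0), rho = numeric(0),
                          has_correlation = FALSE,
                          prior_floored = prior_floored),
                     class = "autocorrelation_model"))
  }

  mu <- mean(vals)
  d2 <- dim(slices$labels[[1]])
  n1 <- stats::nextn(2L * d2[1], 2); n2 <- stats::nextn(2L * d2[2], 2)
  cov_num <- matrix(0, n1, n2); cnt <- matrix(0, n1, n2)
  for (s in seq_along(slices$labels)) {
    m <- masks[[s]] * 1
    g <- (slices$labels[[s]] - mu) * m
    Gp <- matrix(0, n1, n2); Mp <- matrix(0, n1, n2)
    Gp[seq_len(d2[1]), seq_len(d2[2])] <- g
    Mp[seq_len(d2[1]), seq_len(d2[2])] <- m
    FG <- stats::fft(Gp); FM <- stats::fft(Mp)
    cov_num <- cov_num + Re(stats::fft(FG * Conj(FG), inverse = TRUE)) / (n1 * n2)
    cnt <- cnt + Re(stats::fft(FM * Conj(FM), inverse = TRUE)) / (n1 * n2)
  }
  # lag grid (circular correlation on zero-padded fields = linear correlation)
  u <- ifelse(seq_len(n1) - 1L <= n1 %/% 2, seq_len(n1) - 1L,
              seq_len(n1) - 1L - n1)
  v <- ifelse(seq_len(n2) - 1L <= n2 %/% 2, seq_len(n2) - 1L,
              seq_len(n2) - 1L - n2)
  dist_mm <- h * sqrt(outer(u^2, v^2, `+`))
  if (is.null(max_lag_mm)) max_lag_mm <- h * min(d2) / 2
  keep <- cnt > 0.5 & dist_mm <= max_lag_mm
  bin <- round(dist_mm[keep] / h)
  num <- tapply(cov_num[keep], bin, sum)
  den <- tapply(cnt[keep], bin, sum)
  lags <- as.numeric(names(num)) * h
  var0 <- num[lags == 0] / den[lags == 0]
  rho <- as.numeric((num / den) / var0)
  wts <- as.numeric(den)

  fit <- stats::optimize(function(L) sum(wts * (rho - exp(-lags / L))^2),
                         interval = c(h / 10, 100 * max(h, max_lag_mm)))
  structure(list(length_mm = fit$minimum, prior = mu,
                 lags_mm = as.numeric(lags), rho = rho,
                 has_correlation = TRUE, prior_floored = FALSE),
            class = "autocorrelation_model")
}

#' @keywords internal
shift2 <- function(M, dy, dz, fill = 0) {
  d <- dim(M)
  out <- matrix(fill, d[1], d[2])
  ys <- seq_len(d[1]); zs <- seq_len(d[2])
  ysrc <- ys + dy; zsrc <- zs + dz
  oky <- ysrc >= 1L & ysrc <= d[1]; okz <- zsrc >= 1L & zsrc <= d[2]
  out[ys[oky], zs[okz]] <- M[ysrc[oky], zsrc[okz]]
  out
}

#' Wiener (simple-kriging) interpolation of histology slices
#'
#' The probability volume is the simple-kriging predictor
#' `p(x) = m + k(x)' K^-1 (y - m)` under the exponential autocorrelation
#' model, with the data restricted to the two slices nearest in the axial
#' direction and, per slice, the in-plane pixels within `in_plane_radius_mm`
#' of the target position. Because the stencil geometry repeats across every
#' axial layer, the kriging weights are computed once per distinct axial-gap
#' configuration and applied as a linear filter over the slice images. Voxels
#' on a slice reproduce their observed label; far from all slices the
#' prediction decays to the prior `m`.
#'
#' @param slices A `histology_slices` object (slice images are full-plane
#'   labels; pixels outside the prostate cross-section count as benign).
#' @param model An `autocorrelation_model`.
#' @param grid_shape 3-vector; axial layers indexed by `slices$slice_index`.
#' @param in_plane_radius_mm In-plane stencil support (default 3 correlation
#'   lengths; 0 selects the 2-point axial-only stencil).
#' @param jitter Diagonal jitter added when the stencil covariance is not
#'   positive definite (with a warning).
#' @return 3D array of probabilities clipped to [0, 1].
#' @export
wiener_interpolate <- function(slices, model, grid_shape,
                               in_plane_radius_mm = NULL, jitter = 1e-8) {
  stopifnot(inherits(model, "autocorrelation_model"))
  d <- as.integer(grid_shape)
  h <- slices$pixel_spacing_mm
  m <- model$prior
  if (!model$has_correlation) {
    p <- array(m, dim = d)
    for (s in seq_along(slices$slice_index)) {
      p[slices$slice_index[s], , ] <- slices$labels[[s]] * 1
    }
    return(pmin(pmax(p, 0), 1))
  }
  L <- model$length_mm
  if (is.null(in_plane_radius_mm)) in_plane_radius_mm <- 3 * L

  rv <- floor(in_plane_radius_mm / h + 1e-9)
  og <- as.matrix(expand.grid(dy = -rv:rv, dz = -rv:rv))
  og <- og[og[, 1]^2 + og[, 2]^2 <= (in_plane_radius_mm / h + 1e-9)^2, ,
           drop = FALSE]
  sl <- slices$slice_index
  sx <- slices$slice_x_mm

  p <- array(NA_real_, dim = d)
  # axial coordinate of every layer: layer i sits (i - sl[1]) voxels from the
  # first slice
  x_mm <- sx[1] + (seq_len(d[1]) - sl[1]) * h

  cache <- new.env(parent = emptyenv())
  n_off <- nrow(og)
  for (ix in seq_len(d[1])) {
    gaps <- abs(x_mm[ix] - sx)
    use <- order(gaps)[seq_len(min(2L, length(sl)))]
    # slice axial positions carry sign relative to the target layer: weights
    # depend only on this signed-position pattern, so cache on it
    pos <- sx[use] - x_mm[ix]
    key <- paste(round(pos, 9), collapse = "_")
    w <- cache[[key]]
    if (is.null(w)) {
      ns <- length(use)
      pts_dy <- rep(og[, 1], ns); pts_dz <- rep(og[, 2], ns)
      pts_x <- rep(pos, each = n_off)
      np <- ns * n_off
      dxp <- outer(pts_x, pts_x, `-`)
      dyp <- outer(pts_dy, pts_dy, `-`) * h
      dzp <- outer(pts_dz, pts_dz, `-`) * h
      K <- exp(-sqrt(dxp^2 + dyp^2 + dzp^2) / L)
      k <- exp(-sqrt(pts_x^2 + (pts_dy * h)^2 + (pts_dz * h)^2) / L)
      ch <- tryCatch(chol(K), error = function(e) NULL)
      if (is.null(ch)) {
        warning("stencil covariance not positive definite: jitter added")
        ch <- chol(K + diag(jitter, np))
      }
      w <- backsolve(ch, backsolve(ch, k, transpose = TRUE))
      w <- matrix(w, nrow = n_off)           # column per slice in `use`
      cache[[key]] <- w
    }
    layer <- matrix(0, d[2], d[3])
    for (si in seq_along(use)) {
      G <- slices$labels[[use[si]]] - m
      for (oi in seq_len(n_off)) {
        wi <- w[oi, si]
        if (abs(wi) < 1e-14) next
        layer <- layer + wi * shift2(G, og[oi, 1], og[oi, 2], fill = 0)
      }
    }
    p[ix, , ] <- m + layer
  }
  pmin(pmax(p, 0), 1)
}

#' Voxel confidence weights from reference probabilities
#'
#' `w = alpha / (p (1 - p) + alpha)`: certain voxels (p near 0 or 1) get full
#' weight, maximally uncertain voxels (p = 0.5) the minimum
#' `alpha / (0.25 + alpha)`.
#'
#' @param p Probability array in [0, 1].
#' @param alpha Regularisation constant, default 0.2.
#' @return Weight array in (alpha/(0.25+alpha), 1].
#' @export
confidence_weights <- function(p, alpha = 0.2) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("alpha must be a positive scalar")
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  alpha / (p * (1 - p) + alpha)
}

#' Hard labels from reference probabilities
#'
#' @param p Probability array.
#' @return Integer array, 1 where `p >= 0.5`.
#' @export
binarize_reference <- function(p) {
  array((p >= 0.5) * 1L, dim = dim(p))
}

#' Build the full voxel-wise reference standard for a study
#'
#' Runs [estimate_slice_autocorrelation], [wiener_interpolate],
#' [binarize_reference] and [confidence_weights] and bundles the results with
#' the anatomy masks.
#'
#' @param study A `phantom_study` with `histology_slices`.
#' @param alpha Confidence-weight regularisation constant (default 0.2).
#' @param in_plane_radius_mm Optional kriging support override.
#' @return A `reference_volume`: arrays `p`, `label`, `weight`, the model and
#'   the prostate/pz/tz masks.
#' @export
build_reference <- function(study, alpha = 0.2, in_plane_radius_mm = NULL) {
  stopifnot(inherits(study, "phantom_study"), !is.null(study$histology_slices))
  model <- estimate_slice_autocorrelation(study$histology_slices)
  p <- wiener_interpolate(study$histology_slices, model, study$grid$shape,
                          in_plane_radius_mm = in_plane_radius_mm)
  structure(list(p = p, label = binarize_reference(p),
                 weight = confidence_weights(p, alpha), model = model,
                 prostate_mask = study$prostate_mask, pz_mask = study$pz_mask,
                 tz_mask = study$tz_mask),
            class = "reference_volume")
}
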