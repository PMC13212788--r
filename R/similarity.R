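# Spatiotemporal similarity analysis: per voxel, how alike a TIC is to the
# TICs on a surrounding ring — Pearson correlation in the time domain, Welch
# magnitude-squared coherence in the frequency domain, and plug-in mutual
# information from pooled amplitude pairs. More coherent microvascular
# patches produce more similar neighbouring TICs.

#' @keywords internal
ring_offsets <- function(ring_radius_mm, voxel_size_mm) {
  if (ring_radius_mm < voxel_size_mm) {
    stop("ring radius must be at least one voxel")
  }
  off <- offsets_within_radius(ring_radius_mm, voxel_size_mm,
                               shell_tol_mm = voxel_size_mm / 2)
  if (!nrow(off)) stop("ring contains no voxel offsets")
  off
}

# Restrict the analysis to the contrast passage: [appearance, appearance + win]
# on the mean masked TIC (appearance = first 5%-of-peak crossing).
#' @keywords internal
similarity_frames <- function(ticvol, window_s = 60) {
  t <- ticvol$time_s
  m <- matrix(ticvol$data, ncol = length(t))[which(ticvol$mask), , drop = FALSE]
  if (!nrow(m)) return(seq_along(t))
  mtic <- colMeans(m)
  pk <- max(mtic)
  if (pk <= 0) return(seq_along(t))
  start <- which(mtic >= 0.05 * pk)[1]
  keep <- which(t >= t[start] & t <= t[start] + window_s)
  if (length(keep) < 8L) keep <- seq_along(t)
  keep
}

# Internal workhorse shared by the three maps: builds the masked row matrix
# and the centre->neighbour row lookup per ring offset.
#' @keywords internal
similarity_context <- function(ticvol, ring_radius_mm, window_s = 60) {
  d <- dim(ticvol$data)[1:3]
  frames <- similarity_frames(ticvol, window_s)
  idx <- which(ticvol$mask)
  nt <- dim(ticvol$data)[4]
  Y <- matrix(ticvol$data, ncol = nt)[idx, frames, drop = FALSE]
  row_of <- array(NA_integer_, dim = d)
  row_of[idx] <- seq_along(idx)
  off <- ring_offsets(ring_radius_mm, ticvol$voxel_size_mm)
  ijk <- arrayInd(idx, d)
  neigh <- matrix(NA_integer_, nrow = length(idx), ncol = nrow(off))
  for (o in seq_len(nrow(off))) {
    nij <- sweep(ijk, 2, off[o, ], `+`)
    ok <- nij[, 1] >= 1 & nij[, 1] <= d[1] & nij[, 2] >= 1 & nij[, 2] <= d[2] &
      nij[, 3] >= 1 & nij[, 3] <= d[3]
    lin <- rep(NA_integer_, length(idx))
    lin[ok] <- vox_linear_index(nij[ok, , drop = FALSE], d)
    neigh[, o] <- ifelse(ok, row_of[ifelse(is.na(lin), 1L, lin)], NA_integer_)
    neigh[!ok, o] <- NA_integer_
  }
  list(d = d, idx = idx, Y = Y, neigh = neigh, frames = frames)
}

#' Map of mean neighbour TIC correlation (time domain)
#'
#' For every masked voxel, the Pearson correlation between the centre TIC and
#' each TIC on the ring of radius `ring_radius_mm`, averaged over neighbours.
#' Zero-variance pairs are skipped; voxels with no usable pair are missing.
#' TICs are restricted to the contrast passage (appearance to appearance +
#' `window_s`).
#'
#' @param ticvol A [tic_volume].
#' @param ring_radius_mm Ring radius (mm), at least one voxel.
#' @param window_s Analysis window after contrast appearance (s).
#' @return 3D array of mean correlations in `[-1, 1]`.
#' @export
tic_correlation_map <- function(ticvol, ring_radius_mm = 2, window_s = 60) {
  ctx <- similarity_context(ticvol, ring_radius_mm, window_s)
  Yc <- ctx$Y - rowMeans(ctx$Y)
  sd_r <- sqrt(rowSums(Yc^2))
  usable <- sd_r > 0
  acc <- numeric(nrow(Yc))
  cnt <- numeric(nrow(Yc))
  for (o in seq_len(ncol(ctx$neigh))) {
    nb <- ctx$neigh[, o]
    ok <- !is.na(nb)
    ok[ok] <- usable[nb[ok]] & usable[which(ok)]
    if (!any(ok)) next
    num <- rowSums(Yc[ok, , drop = FALSE] * Yc[nb[ok], , drop = FALSE])
    r <- num / (sd_r[ok] * sd_r[nb[ok]])
    acc[ok] <- acc[ok] + r
    cnt[ok] <- cnt[ok] + 1
  }
  out <- array(NA_real_, dim = ctx$d)
  val <- ifelse(cnt > 0, acc / cnt, NA_real_)
  out[ctx$idx] <- val
  out
}

#' Map of mean neighbour magnitude-squared coherence (frequency domain)
#'
#' Welch-style magnitude-squared coherence between the centre TIC and each
#' ring TIC: Hann-windowed overlapping segments, cross- and auto-spectra
#' averaged over segments, coherence averaged over the frequency band and over
#' neighbours.
#'
#' @inheritParams tic_correlation_map
#' @param band_hz Length-2 frequency band (Hz) over which coherence is
#'   averaged; defaults to the full band excluding DC. Must lie within
#'   Nyquist.
#' @param segment_length Welch segment length (samples); default the largest
#'   power of two not exceeding half the window, at least 8.
#' @return 3D array of mean coherences in `[0, 1]`.
#' @export
tic_coherence_map <- function(ticvol, ring_radius_mm = 2, band_hz = NULL,
                              window_s = 60, segment_length = NULL) {
  ctx <- similarity_context(ticvol, ring_radius_mm, window_s)
  nt <- ncol(ctx$Y)
  dt <- diff(ticvol$time_s[1:2])
  fs <- 1 / dt
  if (is.null(segment_length)) {
    segment_length <- max(8L, 2^floor(log2(nt / 2)))
  }
  L <- as.integer(segment_length)
  if (L > nt) stop("TIC shorter than two spectral windows")
  step <- max(1L, L %/% 2L)
  starts <- seq(1L, nt - L + 1L, by = step)
  freqs <- (0:(L - 1)) / (L * dt)
  if (is.null(band_hz)) band_hz <- c(freqs[2], fs / 2)
  if (band_hz[2] > fs / 2 + 1e-12 || band_hz[1] < 0) {
    stop("band outside the Nyquist range")
  }
  bins <- which(freqs >= band_hz[1] - 1e-12 & freqs <= band_hz[2] + 1e-12)
  if (!length(bins)) stop("band contains no frequency bins")
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))   # Hann

  # segment FFTs for all rows (detrended per segment, windowed)
  Z <- vector("list", length(starts))
  for (s in seq_along(starts)) {
    seg <- ctx$Y[, starts[s]:(starts[s] + L - 1), drop = FALSE]
    seg <- seg - rowMeans(seg)
    seg <- sweep(seg, 2, win, `*`)
    Z[[s]] <- t(stats::mvfft(t(seg)))[, bins, drop = FALSE]
  }

  n_row <- nrow(ctx$Y)
  acc <- numeric(n_row); cnt <- numeric(n_row)
  Sxx <- Reduce(`+`, lapply(Z, function(z) Mod(z)^2))
  for (o in seq_len(ncol(ctx$neigh))) {
    nb <- ctx$neigh[, o]
    ok <- which(!is.na(nb))
    if (!length(ok)) next
    Sxy <- 0
    for (s in seq_along(Z)) {
      Sxy <- Sxy + Z[[s]][ok, , drop = FALSE] * Conj(Z[[s]][nb[ok], , drop = FALSE])
    }
    den <- Sxx[ok, , drop = FALSE] * Sxx[nb[ok], , drop = FALSE]
    msc <- Mod(Sxy)^2 / pmax(den, 1e-300)
    good <- den > 0
    mval <- rowSums(ifelse(good, msc, 0)) / pmax(rowSums(good), 1)
    has <- rowSums(good) > 0
    acc[ok[has]] <- acc[ok[has]] + mval[has]
    cnt[ok[has]] <- cnt[ok[has]] + 1
  }
  out <- array(NA_real_, dim = ctx$d)
  out[ctx$idx] <- ifelse(cnt > 0, acc / cnt, NA_real_)
  out
}

#' Map of mean neighbour mutual information
#'
#' Plug-in mutual information (bits) between the centre and each ring TIC,
#' from the joint histogram of amplitude pairs pooled over time samples with
#' per-TIC equal-frequency (quantile) binning, averaged over neighbours.
#' Equal-frequency binning makes the estimate invariant to monotone amplitude
#' transforms.
#'
#' @inheritParams tic_correlation_map
#' @param n_bins Number of amplitude bins per signal (default 16). When the
#'   window holds fewer than `n_bins^2` samples the bins are widened with a
#'   warning.
#' @return 3D array of mean mutual information (bits, >= 0).
#' @export
tic_mutual_information_map <- function(ticvol, ring_radius_mm = 2, n_bins = 16L,
                                       window_s = 60) {
  if (n_bins < 2L) stop("n_bins must be at least 2")
  ctx <- similarity_context(ticvol, ring_radius_mm, window_s)
  nt <- ncol(ctx$Y)
  B <- as.integer(n_bins)
  if (nt < B^2) {
    B <- max(2L, floor(sqrt(nt)))
    warning(sprintf("fewer samples (%d) than n_bins^2; widening bins to %d", nt, B))
  }
  bins <- quantile_bins(ctx$Y, B)
  n_row <- nrow(ctx$Y)
  acc <- numeric(n_row); cnt <- numeric(n_row)
  for (o in seq_len(ncol(ctx$neigh))) {
    nb <- ctx$neigh[, o]
    ok <- which(!is.na(nb))
    if (!length(ok)) next
    mi <- pair_mutual_information(bins[ok, , drop = FALSE],
                                  bins[nb[ok], , drop = FALSE], B)
    acc[ok] <- acc[ok] + mi
    cnt[ok] <- cnt[ok] + 1
  }
  out <- array(NA_real_, dim = ctx$d)
  out[ctx$idx] <- ifelse(cnt > 0, acc / cnt, NA_real_)
  out
}

# Equal-frequency binning per row: bin = ceiling(rank / (n / B)).
#' @keywords internal
quantile_bins <- function(Y, B) {
  n <- ncol(Y)
  nr <- nrow(Y)
  # within-row first-ties ranks via one stable two-key radix sort
  ord <- order(rep(seq_len(nr), n), as.vector(Y), method = "radix")
  rk <- integer(nr * n)
  rk[ord] <- rep.int(seq_len(n), nr)
  rk <- matrix(rk, nr, n)
  b <- ceiling(rk * B / n)
  b[b < 1L] <- 1L
  b[b > B] <- B
  storage.mode(b) <- "integer"
  b
}

# MI in bits for each row pair of two integer bin matrices (n_pairs x n_t).
#' @keywords internal
pair_mutual_information <- function(bx, by, B) {
  n_pairs <- nrow(bx); nt <- ncol(bx)
  joint <- (bx - 1L) * B + by                     # in 1..B^2
  # per-pair histograms by tabulating combined (pair, bin) keys; a zero count
  # contributes 0 * log(.) = 0 to the plug-in entropy
  ent_from_keys <- function(vals, nb) {
    tab <- tabulate((seq_len(n_pairs) - 1L) * nb + vals, nbins = n_pairs * nb)
    P <- matrix(tab, nrow = nb) / nt
    -colSums(P * log2(pmax(P, 1e-300)))
  }
  hj <- ent_from_keys(joint, B * B)
  hx <- ent_from_keys(bx, B)
  hy <- ent_from_keys(by, B)
  pmax(hx + hy - hj, 0)
}

#' Compute all similarity maps
#'
#' @inheritParams tic_correlation_map
#' @param n_bins Bins for the mutual-information map.
#' @param band_hz Band for the coherence map.
#' @return Named list of 3D arrays `corr_time`, `coh_freq`, `mi`.
#' @export
similarity_maps <- function(ticvol, ring_radius_mm = 2, window_s = 60,
                            n_bins = 16L, band_hz = NULL) {
  list(
    corr_time = tic_correlation_map(ticvol, ring_radius_mm, window_s),
    coh_freq = tic_coherence_map(ticvol, ring_radius_mm, band_hz, window_s),
    mi = tic_mutual_information_map(ticvol, ring_radius_mm, n_bins, window_s)
  )
}
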