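# Shared fixtures, memoised so expensive objects are built once per session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- build()
  .fixture_env[[key]]
}

# Small feasible phantom configuration (16^3 grids quantize lesion volumes
# coarsely, so the smoke prevalence target is 7% with a single lesion).
small_phantom_config <- function(seed = 11L) {
  phantom_config_separable(grid_shape = c(16L, 16L, 16L), n_lesions = 1L,
                           target_prevalence = 0.07, seed = seed)
}

small_study <- function() {
  memo("small_study", function() generate_phantom_study(small_phantom_config()))
}

small_patient <- function() {
  memo("small_patient", function()
    suppressWarnings(extract_features(small_study())))
}

small_cohort <- function(n = 4L) {
  memo(paste0("cohort", n), function()
    lapply(seq_len(n), function(i) {
      st <- generate_phantom_study(small_phantom_config(seed = 100L + i))
      suppressWarnings(extract_features(st))
    }))
}

tiny_train_config <- function(...) {
  benchmark_train_config(max_epochs = 3L, patience = 2L,
                         pretrain_pos_cap = 80L, finetune_cap = 300L,
                         val_cap = 300L, pretrain_val_cap = 120L, ...)
}

# Analytic mLDRW curve on a time grid for a parameter matrix.
mldrw_truth_curves <- function(theta, t) {
  n <- nrow(theta)
  Y <- matrix(0, n, length(t))
  for (i in seq_len(n)) {
    fit <- list(kappa = theta[i, 1], mu = theta[i, 2], t0 = theta[i, 3],
                auc = theta[i, 4])
    class(fit) <- "mldrw_fit"
    Y[i, ] <- mldrw_curve(fit, t)
  }
  Y
}

# Quadratic-time weighted Mann-Whitney AUC oracle with the 1/2 tie convention.
auc_oracle <- function(scores, labels, weights) {
  pos <- which(labels > 0); neg <- which(labels <= 0)
  num <- 0
  for (i in pos) {
    gt <- scores[i] > scores[neg]
    eq <- scores[i] == scores[neg]
    num <- num + weights[i] * sum(weights[neg] * (gt + 0.5 * eq))
  }
  num / (sum(weights[pos]) * sum(weights[neg]))
}

# Synthetic uniform-direction velocity field (one elevation band).
synthetic_direction_field <- function(az, dims) {
  stopifnot(length(az) == prod(dims))
  f <- list(sx = array(NA_real_, dims), sy = array(NA_real_, dims),
            sz = array(NA_real_, dims),
            dx = array(cos(az), dims), dy = array(sin(az), dims),
            dz = array(0, dims),
            v_mag = array(1, dims), valid = array(TRUE, dims))
  class(f) <- "velocity_field"
  f
}

# One noiseless shear-wave plane with a constant propagation speed.
constant_speed_plane <- function(c_mps = 2, n_lat = 9L, n_ax = 4L,
                                 dx_mm = 1, prf_hz = 1e4,
                                 pulse_sigma_s = 4e-4) {
  # lead-in keeps every pulse fully supported inside the movie
  delays <- 6 * pulse_sigma_s + seq_len(n_lat) * (dx_mm / 1000) / c_mps
  t_total <- max(delays) + 8 * pulse_sigma_s
  times <- seq(0, t_total, by = 1 / prf_hz)
  pv <- array(0, dim = c(n_ax, n_lat, length(times)))
  for (j in seq_len(n_lat)) {
    pulse <- exp(-(times - delays[j])^2 / (2 * pulse_sigma_s^2))
    pv[, j, ] <- matrix(pulse, n_ax, length(times), byrow = TRUE)
  }
  list(particle_velocity = pv, lateral_spacing_mm = dx_mm,
       frame_interval_s = 1 / prf_hz, pose_rad = 0,
       axial_mm = seq_len(n_ax), lateral_radius_mm = seq_len(n_lat) * dx_mm)
}

# Histology-style slice list over a d2 x d3 in-plane grid.
make_slices <- function(labels, slice_index, pixel_spacing_mm = 2,
                        prostate = NULL) {
  structure(list(labels = labels, prostate = prostate,
                 slice_index = as.integer(slice_index),
                 slice_x_mm = (slice_index - 1) * pixel_spacing_mm,
                 spacing_mm = diff(slice_index)[1] * pixel_spacing_mm,
                 pixel_spacing_mm = pixel_spacing_mm),
            class = "histology_slices")
}
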