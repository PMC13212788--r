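# Shared numerical helpers: seeded RNG fan-out, array geometry, moving sums,
# and a batched solver for small symmetric systems used by several estimators.

#' Derive a stage-specific seed from a global seed
#'
#' All stochastic stages draw their seed from one global seed plus a stage tag,
#' so individual stages are reproducible in isolation and two stages never
#' share an RNG stream.
#'
#' @param seed Integer global seed.
#' @param tag Character stage tag.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(tag)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Voxel-centre world coordinates (mm) for a grid. The probe sits at the world
# origin; x runs along the probe axis (base to apex), z points anterior (away
# from the probe), y lateral. The grid is centred on `centre_mm`.
#' @keywords internal
grid_coordinates <- function(grid_shape, voxel_size_mm, centre_mm) {
  ax <- lapply(1:3, function(a) {
    (seq_len(grid_shape[a]) - (grid_shape[a] + 1) / 2) * voxel_size_mm + centre_mm[a]
  })
  names(ax) <- c("x", "y", "z")
  ax
}

#' @keywords internal
coord_arrays <- function(grid_shape, voxel_size_mm, centre_mm) {
  ax <- grid_coordinates(grid_shape, voxel_size_mm, centre_mm)
  list(
    x = array(rep(ax$x, times = grid_shape[2] * grid_shape[3]), dim = grid_shape),
    y = array(rep(rep(ax$y, each = grid_shape[1]), times = grid_shape[3]), dim = grid_shape),
    z = array(rep(ax$z, each = grid_shape[1] * grid_shape[2]), dim = grid_shape)
  )
}

# Shift a 3D array by integer voxel offsets, padding with `fill`.
#' @keywords internal
shift_array <- function(a, offset, fill = NA_real_) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    o <- offset[k]
    if (o >= d[k] || o <= -d[k]) return(out)
    if (o >= 0) {
      dst[[k]] <- (1 + o):d[k]
      src[[k]] <- 1:(d[k] - o)
    } else {
      dst[[k]] <- 1:(d[k] + o)
      src[[k]] <- (1 - o):d[k]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Moving (box) sum along one axis of a 3D array with window half-width `hw`,
# zero-padded at the borders. Separable application gives 3D box sums.
#' @keywords internal
box_sum_axis <- function(a, hw, axis) {
  if (hw == 0L) return(a)
  d <- dim(a)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  cs <- apply(m, 2, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, nrow = d[axis])
  n <- d[axis]
  idx_hi <- pmin(seq_len(n) + hw, n)
  idx_lo <- seq_len(n) - hw - 1L
  out <- cs[idx_hi, , drop = FALSE]
  pos <- idx_lo >= 1L
  if (any(pos)) out[pos, ] <- out[pos, , drop = FALSE] - cs[idx_lo[pos], , drop = FALSE]
  res <- array(out, dim = d[perm])
  aperm(res, order(perm))
}

#' @keywords internal
box_sum3 <- function(a, hw) {
  box_sum_axis(box_sum_axis(box_sum_axis(a, hw, 1L), hw, 2L), hw, 3L)
}

# Batched Cholesky solve for n symmetric positive-definite 4x4 systems.
# K is given as a list/matrix of its 10 lower-triangle entries, each a vector
# of length n, ordered (11,21,31,41,22,32,42,33,43,44); b is an n x 4 matrix.
# Returns list(x = n x 4 solutions, ok = logical, pivots = n x 4 Cholesky
# diagonal entries). Systems with a non-positive pivot get ok = FALSE.
#' @keywords internal
batch_solve_sym4 <- function(K, b, eps = 1e-300) {
  k11 <- K[[1]]; k21 <- K[[2]]; k31 <- K[[3]]; k41 <- K[[4]]
  k22 <- K[[5]]; k32 <- K[[6]]; k42 <- K[[7]]
  k33 <- K[[8]]; k43 <- K[[9]]; k44 <- K[[10]]

  ok <- k11 > eps
  l11 <- sqrt(pmax(k11, eps))
  l21 <- k21 / l11; l31 <- k31 / l11; l41 <- k41 / l11
  d2 <- k22 - l21^2
  ok <- ok & (d2 > eps)
  l22 <- sqrt(pmax(d2, eps))
  l32 <- (k32 - l31 * l21) / l22
  l42 <- (k42 - l41 * l21) / l22
  d3 <- k33 - l31^2 - l32^2
  ok <- ok & (d3 > eps)
  l33 <- sqrt(pmax(d3, eps))
  l43 <- (k43 - l41 * l31 - l42 * l32) / l33
  d4 <- k44 - l41^2 - l42^2 - l43^2
  ok <- ok & (d4 > eps)
  l44 <- sqrt(pmax(d4, eps))

  # forward substitution L y = b
  y1 <- b[, 1] / l11
  y2 <- (b[, 2] - l21 * y1) / l22
  y3 <- (b[, 3] - l31 * y1 - l32 * y2) / l33
  y4 <- (b[, 4] - l41 * y1 - l42 * y2 - l43 * y3) / l44
  # back substitution L' x = y
  x4 <- y4 / l44
  x3 <- (y3 - l43 * x4) / l33
  x2 <- (y2 - l32 * x3 - l42 * x4) / l22
  x1 <- (y1 - l21 * x2 - l31 * x3 - l41 * x4) / l11

  list(
    x = cbind(x1, x2, x3, x4, deparse.level = 0),
    ok = ok & is.finite(x1) & is.finite(x2) & is.finite(x3) & is.finite(x4),
    pivots = cbind(l11, l22, l33, l44, deparse.level = 0)
  )
}

# Gaussian smoothing of a 3D array by separable convolution (sigma in voxels,
# zero-phase, kernel truncated at 3 sigma, renormalised at borders).
#' @keywords internal
gaussian_smooth3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  kern <- exp(-((-r):r)^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  ones <- array(1, dim = dim(a))
  num <- a
  den <- ones
  for (axis in 1:3) {
    num <- conv_axis(num, kern, axis)
    den <- conv_axis(den, kern, axis)
  }
  num / den
}

#' @keywords internal
conv_axis <- function(a, kern, axis) {
  d <- dim(a)
  r <- (length(kern) - 1L) / 2L
  out <- array(0, dim = d)
  for (i in seq_along(kern)) {
    o <- i - r - 1L
    off <- c(0L, 0L, 0L)
    off[axis] <- o
    out <- out + kern[i] * shift_array(a, off, fill = 0)
  }
  out
}

# Linear voxel index helpers
#' @keywords internal
vox_linear_index <- function(ijk, d) {
  (ijk[, 3] - 1L) * d[1] * d[2] + (ijk[, 2] - 1L) * d[1] + ijk[, 1]
}

#' @keywords internal
offsets_within_radius <- function(radius_mm, voxel_size_mm, include_centre = FALSE,
                                  shell_tol_mm = NULL) {
  r_vox <- ceiling(radius_mm / voxel_size_mm)
  g <- expand.grid(i = -r_vox:r_vox, j = -r_vox:r_vox, k = -r_vox:r_vox)
  dist <- sqrt(g$i^2 + g$j^2 + g$k^2) * voxel_size_mm
  if (is.null(shell_tol_mm)) {
    keep <- dist <= radius_mm + 1e-9
  } else {
    keep <- abs(dist - radius_mm) <= shell_tol_mm + 1e-9
  }
  if (!include_centre) keep <- keep & dist > 1e-12
  as.matrix(g[keep, , drop = FALSE])
}

#' @keywords internal
dilate_mask <- function(mask, n_vox) {
  out <- mask
  for (axis in 1:3) {
    acc <- out
    for (o in seq_len(n_vox)) {
      off <- c(0L, 0L, 0L)
      off[axis] <- o
      acc <- acc | shift_array(out, off, fill = FALSE) | shift_array(out, -off, fill = FALSE)
    }
    out <- acc
  }
  out
}

#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
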