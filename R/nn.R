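# Minimal neural-network engine: valid 3D convolutions via im2col with cached
# index tables, dense layers, ReLU/sigmoid, Adam, and the confidence-weighted
# binary cross-entropy. Activations are stored as (n_samples * n_spatial) x
# n_channels matrices with the spatial index fastest, so convolution is a
# gather followed by one BLAS matmul.

#' @keywords internal
.im2col_cache <- new.env(parent = emptyenv())

#' Valid-convolution output geometry and gather table
#'
#' For an input spatial shape and kernel edge `k`, returns the output shape
#' and the (n_out x k^3) table of input linear indices feeding each output
#' position. Tables are cached per shape.
#'
#' @keywords internal
conv_geometry <- function(dim_in, k = 3L) {
  key <- paste(c(dim_in, k), collapse = "_")
  got <- .im2col_cache[[key]]
  if (!is.null(got)) return(got)
  d <- as.integer(dim_in)
  dout <- d - k + 1L
  if (any(dout < 1L)) stop("input smaller than the kernel")
  oi <- as.matrix(expand.grid(i = seq_len(dout[1]), j = seq_len(dout[2]),
                              k = seq_len(dout[3])))
  tap <- as.matrix(expand.grid(a = 0:(k - 1L), b = 0:(k - 1L), c = 0:(k - 1L)))
  idx <- matrix(0L, nrow(oi), nrow(tap))
  for (t in seq_len(nrow(tap))) {
    idx[, t] <- (oi[, 1] + tap[t, 1]) +
      (oi[, 2] + tap[t, 2] - 1L) * d[1] +
      (oi[, 3] + tap[t, 3] - 1L) * d[1] * d[2]
  }
  out <- list(dim_out = dout, idx = idx, n_in = as.integer(prod(d)),
              n_out = as.integer(prod(dout)), k3 = nrow(tap))
  .im2col_cache[[key]] <- out
  out
}

#' @keywords internal
batch_rowmap <- function(geom, n_batch) {
  key <- paste(c(geom$n_in, geom$n_out, geom$k3, n_batch), collapse = "_rm_")
  got <- .im2col_cache[[key]]
  if (!is.null(got)) return(got)
  rm <- geom$idx[rep(seq_len(geom$n_out), n_batch), , drop = FALSE] +
    rep((seq_len(n_batch) - 1L) * geom$n_in, each = geom$n_out)
  attr(rm, "vec") <- as.integer(rm)
  .im2col_cache[[key]] <- rm
  rm
}

#' 3D valid convolution, forward pass
#'
#' @param A Activation matrix, (n_batch * n_spatial_in) x c_in.
#' @param W Kernel matrix, (k^3 * c_in) x c_out, rows ordered tap-fastest
#'   within channel.
#' @param b Bias vector, length c_out.
#' @param geom From [conv_geometry] for the input spatial shape.
#' @param n_batch Number of samples stacked in `A`.
#' @return List: `out` ((n_batch * n_spatial_out) x c_out), `cols` (cached for
#'   the backward pass).
#' @keywords internal
conv3d_forward <- function(A, W, b, geom, n_batch) {
  c_in <- ncol(A)
  k3 <- geom$k3
  rm <- batch_rowmap(geom, n_batch)
  # single gather: stacking the tap blocks row-wise and reinterpreting the
  # dimensions yields exactly the tap-fastest-within-channel column order
  cols <- .Call(C_gather_cols, A, attr(rm, "vec"), nrow(rm), k3)
  out <- cols %*% W
  out <- out + rep(b, each = nrow(out))
  list(out = out, cols = cols)
}

#' 3D valid convolution, backward pass
#'
#' @param dY Gradient at the output, same shape as `out`.
#' @param cols Cached im2col matrix from the forward pass.
#' @param W Kernel matrix.
#' @param geom,n_batch As in [conv3d_forward].
#' @param need_dA Skip the input-gradient scatter for the first layer.
#' @return List: `dW`, `db`, `dA` (or NULL).
#' @keywords internal
conv3d_backward <- function(dY, cols, W, geom, n_batch, need_dA = TRUE) {
  dW <- crossprod(cols, dY)
  db <- colSums(dY)
  dA <- NULL
  if (need_dA) {
    c_in <- nrow(W) / geom$k3
    dcols <- tcrossprod(dY, W)
    rm <- batch_rowmap(geom, n_batch)
    # for a fixed tap the output->input row map is injective, so indexed
    # accumulation is safe; taps are applied in index order
    dA <- .Call(C_scatter_add, matrix(0, n_batch * geom$n_in, c_in),
                attr(rm, "vec"), dcols, geom$k3)
  }
  list(dW = dW, db = db, dA = dA)
}

#' @keywords internal
dense_forward <- function(A, W, b) {
  out <- A %*% W
  out + rep(b, each = nrow(out))
}

#' @keywords internal
dense_backward <- function(dY, A, W) {
  list(dW = crossprod(A, dY), db = colSums(dY), dA = tcrossprod(dY, W))
}

#' @keywords internal
relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' @keywords internal
relu_backward <- function(dY, out) {
  dY[out <= 0] <- 0
  dY
}

#' @keywords internal
sigmoid <- function(z) 1 / (1 + exp(-z))

#' Confidence-weighted binary cross-entropy
#'
#' `-sum(w * (y log p + (1-y) log(1-p))) / sum(w)`. Predictions are clipped to
#' `[1e-7, 1 - 1e-7]` before the logarithm.
#'
#' @param pred Predicted probabilities.
#' @param label Binary labels.
#' @param weight Positive voxel weights (default 1).
#' @return Scalar loss.
#' @export
weighted_bce <- function(pred, label, weight = rep(1, length(pred))) {
  stopifnot(length(pred) == length(label), length(weight) == length(pred))
  if (any(weight <= 0)) stop("weights must be positive")
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  -sum(weight * (label * log(p) + (1 - label) * log(1 - p))) / sum(weight)
}

#' @keywords internal
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

#' @keywords internal
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
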