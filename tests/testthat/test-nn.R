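# Finite-difference gradient checks. Parameters are perturbed away from zero
# first so no ReLU input sits on the kink.

test_that("conv3d forward matches a direct dense convolution", {
  set.seed(51)
  dims <- c(5L, 5L, 5L)
  c_in <- 2L; c_out <- 3L
  geom <- mpuscad:::conv_geometry(dims)
  n_batch <- 2L
  A <- matrix(rnorm(n_batch * prod(dims) * c_in), ncol = c_in)
  W <- matrix(rnorm(27 * c_in * c_out), 27 * c_in, c_out)
  b <- rnorm(c_out)
  fw <- mpuscad:::conv3d_forward(A, W, b, geom, n_batch)
  # direct evaluation at one interior output voxel of sample 2
  d_out <- dims - 2L
  ov <- c(2L, 3L, 1L)   # output voxel (1-based within the valid grid)
  taps <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  acc <- b
  for (tt in seq_len(27)) {
    src <- ov + taps[tt, ]
    row <- (n_batch - 1L) * prod(dims) +
      src[1] + (src[2] - 1L) * dims[1] + (src[3] - 1L) * dims[1] * dims[2]
    for (ci in seq_len(c_in)) {
      acc <- acc + A[row, ci] * W[(ci - 1L) * 27 + tt, ]
    }
  }
  out_row <- (n_batch - 1L) * prod(d_out) +
    ov[1] + (ov[2] - 1L) * d_out[1] + (ov[3] - 1L) * d_out[1] * d_out[2]
  expect_equal(fw$out[out_row, ], acc, tolerance = 1e-10)
})

test_that("conv gradients agree with finite differences", {
  set.seed(52)
  dims <- c(5L, 5L, 5L)
  c_in <- 2L; c_out <- 2L
  geom <- mpuscad:::conv_geometry(dims)
  n_batch <- 2L
  A <- matrix(rnorm(n_batch * prod(dims) * c_in), ncol = c_in)
  W <- matrix(rnorm(27 * c_in * c_out, sd = 0.3), 27 * c_in, c_out)
  b <- rnorm(c_out, sd = 0.1)
  loss <- function(W, b, A) {
    f <- mpuscad:::conv3d_forward(A, W, b, geom, n_batch)
    sum(sin(f$out))
  }
  f0 <- mpuscad:::conv3d_forward(A, W, b, geom, n_batch)
  dY <- cos(f0$out)
  gr <- mpuscad:::conv3d_backward(dY, f0$cols, W, geom, n_batch)
  eps <- 1e-6
  for (probe in list(c(1, 1), c(13, 2), c(54, 1))) {
    Wp <- W; Wp[probe[1], probe[2]] <- W[probe[1], probe[2]] + eps
    Wm <- W; Wm[probe[1], probe[2]] <- W[probe[1], probe[2]] - eps
    fd <- (loss(Wp, b, A) - loss(Wm, b, A)) / (2 * eps)
    expect_equal(gr$dW[probe[1], probe[2]], fd, tolerance = 1e-5)
  }
  bp <- b; bp[1] <- b[1] + eps; bm <- b; bm[1] <- b[1] - eps
  fd_b <- (loss(W, bp, A) - loss(W, bm, A)) / (2 * eps)
  expect_equal(gr$db[1], fd_b, tolerance = 1e-5)
})

test_that("end-to-end analytic gradients agree with finite differences", {
  set.seed(53)
  spec <- architecture_spec(
    branches = list(g1 = c("a", "b"), g2 = c("c")),
    location = c("l1"), conv_widths = c(3L, 4L), mlp_hidden = c(6L, 5L),
    clinical = c("k1"), expected_param_range = NULL)
  model <- build_model(spec, seed = 2L)
  # perturb every parameter away from ReLU kinks
  model$params <- lapply(model$params, function(p)
    p + rnorm(length(p), sd = 0.05))
  n <- 4L
  patch <- spec$patch
  nl <- length(spec$conv_widths)
  x <- lapply(names(spec$branches), function(g) {
    c_in <- length(spec$branches[[g]]) + 1L
    matrix(rnorm(n * patch^3 * c_in, sd = 0.5), ncol = c_in)
  })
  names(x) <- names(spec$branches)
  clin <- matrix(rnorm(n), n, 1)
  y <- c(1, 0, 1, 0); w <- runif(n, 0.5, 1)
  dims0 <- rep(patch, 3L)
  fwd <- function(params, keep_cache = FALSE) {
    br <- lapply(names(spec$branches), function(g)
      mpuscad:::branch_forward(params, g, x[[g]], dims0, n, nl,
                               keep_cache = keep_cache))
    names(br) <- names(spec$branches)
    X <- cbind(do.call(cbind, lapply(br, `[[`, "out")), clin)
    mf <- mpuscad:::mlp_forward(params, X, keep_cache = keep_cache)
    list(loss = weighted_bce(mf$p, y, w), p = mf$p, mf = mf, br = br)
  }
  f0 <- fwd(model$params, keep_cache = TRUE)
  dz <- mpuscad:::fused_bce_grad(f0$p, y, w)
  grads <- mpuscad:::mlp_backward(model$params, dz, f0$mf$cache)
  dX <- attr(grads, "dX")
  e <- spec$embedding
  for (gi in seq_along(spec$branches)) {
    g <- names(spec$branches)[gi]
    dEmb <- dX[, (gi - 1L) * e + seq_len(e), drop = FALSE]
    gb <- mpuscad:::branch_backward(model$params, g, dEmb, f0$br[[g]]$cache,
                                    n, nl)
    grads[names(gb)] <- gb
  }
  eps <- 1e-6
  for (nm in c("g1.conv1.W", "g1.conv2.b", "g2.conv2.W", "mlp.fc1.W",
               "mlp.fc2.b", "mlp.fc3.W")) {
    i <- sample(length(model$params[[nm]]), 1L)
    p <- model$params
    p[[nm]][i] <- p[[nm]][i] + eps
    up <- fwd(p)$loss
    p[[nm]][i] <- p[[nm]][i] - 2 * eps
    dn <- fwd(p)$loss
    fd <- (up - dn) / (2 * eps)
    expect_equal(grads[[nm]][i], fd, tolerance = 1e-4,
                 label = sprintf("analytic gradient of %s[%d]", nm, i))
  }
})

test_that("weighted binary cross-entropy matches its formula and adam descends", {
  p <- c(0.9, 0.2, 0.6); y <- c(1, 0, 1); w <- c(2, 1, 0.5)
  manual <- -sum(w * (y * log(p) + (1 - y) * log(1 - p))) / sum(w)
  expect_equal(weighted_bce(p, y, w), manual, tolerance = 1e-12)
  # adam reduces a quadratic loss
  params <- list(theta = c(3, -2))
  st <- mpuscad:::adam_init(params)
  val <- function(th) sum(th^2)
  v0 <- val(params$theta)
  for (i in 1:200) {
    res <- mpuscad:::adam_step(params, list(theta = 2 * params$theta), st,
                               lr = 0.05)
    params <- res$params; st <- res$state
  }
  expect_lt(val(params$theta), 1e-2 * v0)
})
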