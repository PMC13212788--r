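# Three-branch CNN + MLP voxel classifier: per-feature-group convolutional
# branches produce per-voxel embeddings that a shared MLP head combines with
# clinical scalars into a csPCa probability. Training follows a two-stage
# protocol: branches are pre-trained independently on class-balanced patches,
# then frozen while the MLP is fine-tuned at the true prevalence.

#' Default network architecture
#'
#' Three branches (CUDI temporal, CUDI spatiotemporal, SWE), each a stack of
#' `length(conv_widths)` valid 3x3x3 convolutions over the branch's feature
#' channels plus the location channels, ending in a per-voxel embedding.
#' Embeddings and the clinical scalars feed a two-hidden-layer MLP with a
#' sigmoid output. The default widths put the trainable-parameter count at
#' 46,941.
#'
#' @param branches Named list of per-branch feature-channel names.
#' @param location Location channels appended to every branch input.
#' @param conv_widths Channel widths of the conv stack (last = embedding).
#' @param mlp_hidden MLP hidden-layer widths.
#' @param clinical Clinical scalar names entering the MLP.
#' @param kernel Conv kernel edge (3).
#' @return An `architecture_spec`.
#' @export
architecture_spec <- function(
    branches = list(
      cudi1d = c("kappa", "mu", "t0", "peak", "wash_in"),
      cudi4d = c("cd_vmag", "cd_d", "sa_corr", "sa_coh", "sa_mi",
                 "ve_h", "ve_hcond"),
      swe = c("swe_sws", "swe_e", "swe_quality")),
    location = c("loc_pz", "loc_dist", "loc_elev"),
    conv_widths = c(8L, 12L, 16L),
    mlp_hidden = c(120L, 100L),
    clinical = c("volume_cc", "psa_density"),
    kernel = 3L, expected_param_range = c(46000L, 48000L)) {
  stopifnot(length(branches) >= 1L, length(conv_widths) >= 1L,
            kernel %% 2L == 1L)
  structure(list(branches = branches, location = location,
                 conv_widths = as.integer(conv_widths),
                 mlp_hidden = as.integer(mlp_hidden), clinical = clinical,
                 kernel = as.integer(kernel),
                 expected_param_range = expected_param_range,
                 patch = as.integer(length(conv_widths) * (kernel - 1L) + 1L),
                 embedding = as.integer(conv_widths[length(conv_widths)])),
            class = "architecture_spec")
}

#' @keywords internal
he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

#' Build and initialise a model
#'
#' Deterministic He initialisation for the conv/hidden layers and a scaled
#' initialisation for the sigmoid output, all drawn under the given seed.
#' Warns when the trainable-parameter count falls outside [46,000, 48,000].
#'
#' @param spec An [architecture_spec].
#' @param seed Integer seed.
#' @return A `model_bundle`: `spec`, flat parameter list `params`.
#' @export
build_model <- function(spec = architecture_spec(), seed = 1L) {
  stopifnot(inherits(spec, "architecture_spec"))
  k3 <- spec$kernel^3
  params <- with_seed(derive_seed(seed, "init"), {
    p <- list()
    for (g in names(spec$branches)) {
      c_in <- length(spec$branches[[g]]) + length(spec$location)
      for (l in seq_along(spec$conv_widths)) {
        c_out <- spec$conv_widths[l]
        fan <- k3 * c_in
        p[[paste0(g, ".conv", l, ".W")]] <- he_init(fan, c_out, fan)
        p[[paste0(g, ".conv", l, ".b")]] <- rep(0, c_out)
        c_in <- c_out
      }
    }
    n_in <- spec$embedding * length(spec$branches) + length(spec$clinical)
    widths <- c(n_in, spec$mlp_hidden, 1L)
    for (l in seq_len(length(widths) - 1L)) {
      fan <- widths[l]
      sd0 <- if (l == length(widths) - 1L) sqrt(1 / fan) else sqrt(2 / fan)
      p[[paste0("mlp.fc", l, ".W")]] <-
        matrix(stats::rnorm(fan * widths[l + 1L], sd = sd0), fan, widths[l + 1L])
      p[[paste0("mlp.fc", l, ".b")]] <- rep(0, widths[l + 1L])
    }
    p
  })
  model <- structure(list(spec = spec, params = params), class = "model_bundle")
  n <- count_parameters(model)
  rg <- spec$expected_param_range
  if (!is.null(rg) && (n < rg[1] || n > rg[2])) {
    warning(sprintf("trainable-parameter count %d outside [%d, %d]",
                    n, rg[1], rg[2]))
  }
  model
}

#' Count trainable parameters
#'
#' @param model A `model_bundle` (temporary pretraining heads excluded).
#' @return Integer count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, 1L))
}

#' @keywords internal
branch_forward <- function(params, g, A, dims, n_batch, n_layers,
                           keep_cache = FALSE) {
  cache <- list(A0 = if (keep_cache) A else NULL, geoms = list(),
                cols = list(), outs = list())
  d <- dims
  for (l in seq_len(n_layers)) {
    geom <- conv_geometry(d, 3L)
    cf <- conv3d_forward(A, params[[paste0(g, ".conv", l, ".W")]],
                         params[[paste0(g, ".conv", l, ".b")]], geom, n_batch)
    out <- if (l < n_layers) relu(cf$out) else cf$out
    if (keep_cache) {
      cache$geoms[[l]] <- geom
      cache$cols[[l]] <- cf$cols
      cache$outs[[l]] <- out
    }
    A <- out
    d <- geom$dim_out
  }
  list(out = A, dims = d, cache = cache)
}

#' @keywords internal
branch_backward <- function(params, g, dOut, cache, n_batch, n_layers,
                            need_dA = FALSE) {
  grads <- list()
  dY <- dOut
  for (l in rev(seq_len(n_layers))) {
    if (l < n_layers) dY <- relu_backward(dY, cache$outs[[l]])
    bw <- conv3d_backward(dY, cache$cols[[l]],
                          params[[paste0(g, ".conv", l, ".W")]],
                          cache$geoms[[l]], n_batch,
                          need_dA = (l > 1L) || need_dA)
    grads[[paste0(g, ".conv", l, ".W")]] <- bw$dW
    grads[[paste0(g, ".conv", l, ".b")]] <- bw$db
    dY <- bw$dA
  }
  grads
}

#' @keywords internal
mlp_forward <- function(params, X, keep_cache = FALSE) {
  h1 <- relu(dense_forward(X, params[["mlp.fc1.W"]], params[["mlp.fc1.b"]]))
  h2 <- relu(dense_forward(h1, params[["mlp.fc2.W"]], params[["mlp.fc2.b"]]))
  z <- dense_forward(h2, params[["mlp.fc3.W"]], params[["mlp.fc3.b"]])
  p <- sigmoid(z)
  if (keep_cache) list(p = p, cache = list(X = X, h1 = h1, h2 = h2)) else
    list(p = p)
}

#' @keywords internal
mlp_backward <- function(params, dz, cache) {
  g <- list()
  b3 <- dense_backward(dz, cache$h2, params[["mlp.fc3.W"]])
  g[["mlp.fc3.W"]] <- b3$dW; g[["mlp.fc3.b"]] <- b3$db
  d2 <- relu_backward(b3$dA, cache$h2)
  b2 <- dense_backward(d2, cache$h1, params[["mlp.fc2.W"]])
  g[["mlp.fc2.W"]] <- b2$dW; g[["mlp.fc2.b"]] <- b2$db
  d1 <- relu_backward(b2$dA, cache$h1)
  b1 <- dense_backward(d1, cache$X, params[["mlp.fc1.W"]])
  g[["mlp.fc1.W"]] <- b1$dW; g[["mlp.fc1.b"]] <- b1$db
  attr(g, "dX") <- b1$dA
  g
}

#' Training configuration
#'
#' @param lr Adam learning rate.
#' @param batch_size Voxels per batch.
#' @param pretrain_positive_fraction Positive fraction for branch pretraining
#'   (default 0.5).
#' @param finetune_prevalence Positive fraction for MLP fine-tuning
#'   (default 0.05).
#' @param max_epochs,patience Early-stopping schedule: stop when the
#'   validation weighted ROC AUC has not improved for `patience` epochs, when
#'   the loss is unchanged over `patience` epochs, or at `max_epochs`.
#' @param awgn_sigma,offset_range Augmentation strength on standardized
#'   inputs.
#' @param pretrain_pos_cap,finetune_cap,val_cap Per-fold sample-pool caps
#'   (positives for pretraining; total voxels for fine-tuning/validation) that
#'   bound the runtime of a scaled study.
#' @param pretrain_val_cap Total patches in the balanced validation pool used
#'   for branch early stopping (evaluated every epoch, so kept smaller than
#'   `val_cap`).
#' @param seed Integer training seed.
#' @return A `train_config`.
#' @export
train_config <- function(lr = 1e-3, batch_size = 256L,
                         pretrain_positive_fraction = 0.5,
                         finetune_prevalence = 0.05,
                         max_epochs = 100L, patience = 10L,
                         awgn_sigma = 0.1, offset_range = 0.1,
                         pretrain_pos_cap = 1200L, finetune_cap = 20000L,
                         val_cap = 4000L, pretrain_val_cap = 1000L,
                         seed = 1L) {
  stopifnot(pretrain_positive_fraction > 0, pretrain_positive_fraction < 1,
            finetune_prevalence > 0, finetune_prevalence < 1,
            patience < max_epochs)
  structure(as.list(environment()), class = "train_config")
}

#' Stratified patient folds balanced by lesion size
#'
#' Patients are grouped into a no-csPCa subgroup plus lesion-size terciles,
#' shuffled within subgroup under the seed, and dealt round-robin so subgroup
#' proportions match across folds within one patient.
#'
#' @param patient_ids Identifiers.
#' @param lesion_sizes Per-patient lesion volume (0 for no csPCa).
#' @param k Number of folds (default 7).
#' @param seed Integer seed.
#' @return A `fold_plan`: data.frame (patient, subgroup, fold).
#' @export
make_folds <- function(patient_ids, lesion_sizes, k = 7L, seed = 1L) {
  stopifnot(length(patient_ids) == length(lesion_sizes), k >= 2L)
  pos <- lesion_sizes > 0
  sub <- rep("none", length(patient_ids))
  if (any(pos)) {
    qs <- stats::quantile(lesion_sizes[pos], c(1, 2) / 3, type = 1)
    sub[pos] <- c("small", "medium", "large")[
      1L + (lesion_sizes[pos] > qs[1]) + (lesion_sizes[pos] > qs[2])]
  }
  fold <- integer(length(patient_ids))
  offset <- 0L
  with_seed(derive_seed(seed, "folds"), {
    for (s in unique(sub)) {
      ii <- which(sub == s)
      if (length(ii) < k) {
        warning(sprintf("subgroup '%s' has fewer patients (%d) than folds (%d)",
                        s, length(ii), k))
      }
      ii <- ii[sample.int(length(ii))]
      fold[ii] <- ((seq_along(ii) - 1L + offset) %% k) + 1L
      offset <- offset + length(ii)
    }
  })
  structure(data.frame(patient = patient_ids, subgroup = sub, fold = fold,
                       stringsAsFactors = FALSE), class = c("fold_plan",
                                                            "data.frame"))
}

#' Class-controlled batch index stream for one epoch
#'
#' One epoch is a single pass over the minority class; the majority class is
#' undersampled without replacement (recycled if exhausted). Every batch holds
#' exactly `round(batch_size * positive_fraction)` positives.
#'
#' @param labels Binary vector over the sample pool.
#' @param positive_fraction Target positive fraction per batch.
#' @param batch_size Samples per batch.
#' @param seed Integer seed (use a per-epoch derivation for streams).
#' @return List of integer index vectors.
#' @export
sample_batches <- function(labels, positive_fraction, batch_size = 256L,
                           seed = 1L) {
  pos <- which(labels > 0); neg <- which(labels <= 0)
  if (!length(pos) || !length(neg)) stop("both classes must be present")
  n_pos_b <- max(1L, round(batch_size * positive_fraction))
  n_neg_b <- batch_size - n_pos_b
  minority_pos <- positive_fraction <= 0.5
  with_seed(derive_seed(seed, "batches"), {
    pos <- pos[sample.int(length(pos))]
    neg <- neg[sample.int(length(neg))]
    n_batches <- if (minority_pos) max(1L, length(pos) %/% n_pos_b) else
      max(1L, length(neg) %/% n_neg_b)
    take <- function(v, n) {         # recycle when the pool runs dry
      if (n > length(v)) v[1L + (seq_len(n) - 1L) %% length(v)] else v[seq_len(n)]
    }
    lapply(seq_len(n_batches), function(bi) {
      pp <- take(pos, n_pos_b * n_batches)[(bi - 1L) * n_pos_b + seq_len(n_pos_b)]
      nn <- take(neg, n_neg_b * n_batches)[(bi - 1L) * n_neg_b + seq_len(n_neg_b)]
      s <- c(pp, nn)
      s[sample.int(length(s))]
    })
  })
}

#' Augment a standardized input batch
#'
#' Adds element-wise white Gaussian noise and a per-sample, per-feature
#' constant offset drawn uniformly from `[-offset_range, offset_range]`.
#' Labels and weights are untouched by contract.
#'
#' @param x Matrix (rows = spatial x sample or sample, cols = features).
#' @param awgn_sigma Noise standard deviation (>= 0).
#' @param offset_range Offset half-range (>= 0).
#' @param n_batch Number of samples stacked in `x` (rows per sample =
#'   `nrow(x) / n_batch`); offsets are constant within a sample-feature block.
#' @param seed Integer seed.
#' @return Matrix of the same shape.
#' @export
augment <- function(x, awgn_sigma, offset_range, n_batch = nrow(x),
                    seed = 1L) {
  if (awgn_sigma < 0 || offset_range < 0) stop("augmentation scales must be >= 0")
  if (awgn_sigma == 0 && offset_range == 0) return(x)
  with_seed(derive_seed(seed, "augment"), {
    if (awgn_sigma > 0) {
      x <- x + stats::rnorm(length(x), sd = awgn_sigma)
    }
    if (offset_range > 0) {
      off <- matrix(stats::runif(n_batch * ncol(x), -offset_range,
                                 offset_range), n_batch, ncol(x))
      reps <- nrow(x) / n_batch
      x <- x + off[rep(seq_len(n_batch), each = reps), , drop = FALSE]
    }
    x
  })
}

#' @keywords internal
fused_bce_grad <- function(p, y, w) {
  # gradient of weighted_bce wrt the sigmoid pre-activation
  matrix(w * (p - y) / sum(w), ncol = 1)
}

#' Pre-train one convolutional branch
#'
#' Trains the branch plus a temporary linear head on class-balanced patch
#' pools with weighted BCE, augmentation and Adam; early-stops on the
#' validation weighted ROC AUC (patience epochs) or a stalled loss.
#'
#' @param params Parameter list holding the branch weights.
#' @param g Branch name.
#' @param train,val Patch pools: lists with `x` ((n * patch^3) x c_in matrix),
#'   `y`, `w`.
#' @param spec An [architecture_spec].
#' @param config A [train_config].
#' @param trace Collect per-epoch logs.
#' @return List: updated `params` (head dropped), `head`, `history`,
#'   `val_auc`.
#' @export
pretrain_branch <- function(params, g, train, val, spec, config,
                            trace = FALSE) {
  n_layers <- length(spec$conv_widths)
  pd <- rep(spec$patch, 3L)
  n_sp <- spec$patch^3
  n_tr <- nrow(train$x) / n_sp
  head <- with_seed(derive_seed(config$seed, paste0(g, "_head")), list(
    W = matrix(stats::rnorm(spec$embedding, sd = sqrt(1 / spec$embedding)),
               spec$embedding, 1),
    b = 0))
  opt_names <- c(grep(paste0("^", g, "\\.conv"), names(params), value = TRUE))
  state <- adam_init(c(params[opt_names], list(head.W = head$W, head.b = head$b)))

  # the validation pool is static, so its layer-1 im2col is computed once;
  # later layers depend on the evolving weights and are rebuilt per call
  n_val <- nrow(val$x) / n_sp
  geo1 <- conv_geometry(pd, 3L)
  rm1 <- batch_rowmap(geo1, n_val)
  vcols1 <- val$x[as.vector(rm1), , drop = FALSE]
  dim(vcols1) <- c(nrow(rm1), geo1$k3 * ncol(val$x))
  eval_val <- function(par, hd) {
    a <- vcols1 %*% par[[paste0(g, ".conv1.W")]]
    a <- a + rep(par[[paste0(g, ".conv1.b")]], each = nrow(a))
    if (n_layers > 1L) a <- relu(a)
    dd <- geo1$dim_out
    for (l in seq_len(n_layers)[-1L]) {
      geom <- conv_geometry(dd, 3L)
      cf <- conv3d_forward(a, par[[paste0(g, ".conv", l, ".W")]],
                           par[[paste0(g, ".conv", l, ".b")]], geom, n_val)
      a <- if (l < n_layers) relu(cf$out) else cf$out
      dd <- geom$dim_out
    }
    z <- a %*% hd$W + hd$b
    as.numeric(weighted_roc_auc(as.numeric(z), val$y, val$w)$auc)
  }

  best <- list(params = params[opt_names], head = head, auc = -Inf, epoch = 0L)
  history <- list()
  last_losses <- rep(NA_real_, config$patience)
  for (ep in seq_len(config$max_epochs)) {
    batches <- sample_batches(train$y, config$pretrain_positive_fraction,
                              config$batch_size,
                              derive_seed(config$seed, paste0(g, "_ep", ep)))
    ep_loss <- 0
    for (bi in seq_along(batches)) {
      sel <- batches[[bi]]
      rows <- as.vector(outer(seq_len(n_sp), (sel - 1L) * n_sp, `+`))
      xb <- train$x[rows, , drop = FALSE]
      xb <- augment(xb, config$awgn_sigma, config$offset_range,
                    n_batch = length(sel),
                    seed = derive_seed(config$seed,
                                       paste0(g, "_aug", ep, "_", bi)))
      yb <- train$y[sel]; wb <- train$w[sel]
      fw <- branch_forward(params, g, xb, pd, length(sel), n_layers,
                           keep_cache = TRUE)
      z <- fw$out %*% head$W + head$b
      p <- sigmoid(z)
      loss <- weighted_bce(as.numeric(p), yb, wb)
      if (!is.finite(loss)) {
        stop(sprintf("branch '%s' diverged at epoch %d batch %d (loss %s)",
                     g, ep, bi, format(loss)))
      }
      ep_loss <- ep_loss + loss
      dz <- fused_bce_grad(as.numeric(p), yb, wb)
      gr <- list(head.W = crossprod(fw$out, dz), head.b = colSums(dz))
      dEmb <- tcrossprod(dz, head$W)
      gr <- c(gr, branch_backward(params, g, dEmb, fw$cache, length(sel),
                                  n_layers))
      cur <- c(params[opt_names], list(head.W = head$W, head.b = head$b))
      st <- adam_step(cur, gr, state, lr = config$lr)
      state <- st$state
      params[opt_names] <- st$params[opt_names]
      head$W <- st$params$head.W; head$b <- st$params$head.b
    }
    ep_loss <- ep_loss / length(batches)
    val_auc <- eval_val(params, head)
    if (trace) history[[ep]] <- list(epoch = ep, loss = ep_loss,
                                     val_auc = val_auc)
    if (val_auc > best$auc + 1e-12) {
      best <- list(params = params[opt_names], head = head, auc = val_auc,
                   epoch = ep)
    }
    loss_stalled <- sum(is.finite(last_losses)) == config$patience &&
      max(abs(last_losses - ep_loss)) < 1e-9
    last_losses <- c(last_losses[-1L], ep_loss)
    if (ep - best$epoch >= config$patience || loss_stalled) break
  }
  params[names(best$params)] <- best$params
  list(params = params, head = best$head, val_auc = best$auc,
       history = history, epochs_run = ep)
}

#' Fine-tune the MLP head on frozen branch embeddings
#'
#' Only the MLP parameters are updated; batches are drawn at the configured
#' prevalence from precomputed embedding rows. The branch weights are asserted
#' bit-identical afterwards.
#'
#' @param params Full parameter list (branches pretrained).
#' @param train,val Embedding pools: lists with `x` (n x mlp-input matrix),
#'   `y`, `w`.
#' @param spec,config As in [pretrain_branch].
#' @param trace Collect per-epoch logs.
#' @return List: updated `params`, `val_auc`, `history`.
#' @export
finetune_mlp <- function(params, train, val, spec, config, trace = FALSE) {
  branch_names <- grep("^mlp\\.", names(params), value = TRUE, invert = TRUE)
  frozen <- params[branch_names]
  mlp_names <- grep("^mlp\\.", names(params), value = TRUE)
  state <- adam_init(params[mlp_names])

  best <- list(params = params[mlp_names], auc = -Inf, epoch = 0L)
  history <- list()
  last_losses <- rep(NA_real_, config$patience)
  for (ep in seq_len(config$max_epochs)) {
    batches <- sample_batches(train$y, config$finetune_prevalence,
                              config$batch_size,
                              derive_seed(config$seed, paste0("mlp_ep", ep)))
    ep_loss <- 0
    for (bi in seq_along(batches)) {
      sel <- batches[[bi]]
      xb <- augment(train$x[sel, , drop = FALSE], config$awgn_sigma,
                    config$offset_range, n_batch = length(sel),
                    seed = derive_seed(config$seed, paste0("mlp_aug", ep, "_", bi)))
      fw <- mlp_forward(params, xb, keep_cache = TRUE)
      loss <- weighted_bce(as.numeric(fw$p), train$y[sel], train$w[sel])
      if (!is.finite(loss)) stop(sprintf("MLP diverged at epoch %d", ep))
      ep_loss <- ep_loss + loss
      dz <- fused_bce_grad(as.numeric(fw$p), train$y[sel], train$w[sel])
      gr <- mlp_backward(params, dz, fw$cache)
      st <- adam_step(params[mlp_names], gr, state, lr = config$lr)
      state <- st$state
      params[mlp_names] <- st$params
    }
    ep_loss <- ep_loss / length(batches)
    val_p <- mlp_forward(params, val$x)$p
    val_auc <- as.numeric(weighted_roc_auc(as.numeric(val_p), val$y,
                                           val$w)$auc)
    if (trace) history[[ep]] <- list(epoch = ep, loss = ep_loss,
                                     val_auc = val_auc)
    if (val_auc > best$auc + 1e-12) {
      best <- list(params = params[mlp_names], auc = val_auc, epoch = ep)
    }
    loss_stalled <- sum(is.finite(last_losses)) == config$patience &&
      max(abs(last_losses - ep_loss)) < 1e-9
    last_losses <- c(last_losses[-1L], ep_loss)
    if (ep - best$epoch >= config$patience || loss_stalled) break
  }
  params[mlp_names] <- best$params
  if (!identical(params[branch_names], frozen)) {
    stop("branch weights changed during MLP fine-tuning")
  }
  list(params = params, val_auc = best$auc, history = history,
       epochs_run = ep)
}

#' Greedy forward feature selection
#'
#' Adds, at each step, the candidate whose inclusion maximises the evaluator's
#' mean validation AUC; stops when the best improvement is at most `epsilon`.
#'
#' @param candidates Character vector of candidate names.
#' @param eval_fn `function(selected_set) -> mean validation AUC`.
#' @param epsilon Minimum improvement to continue (default 0.001).
#' @return List: `selected`, `trace` (data.frame of step, candidate, auc,
#'   accepted).
#' @export
forward_feature_selection <- function(candidates, eval_fn, epsilon = 0.001) {
  stopifnot(length(candidates) >= 2L)
  selected <- character(0)
  best_auc <- -Inf
  rows <- list()
  step <- 0L
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    step <- step + 1L
    aucs <- vapply(remaining, function(cnd) eval_fn(c(selected, cnd)), 1)
    top <- which.max(aucs)
    improved <- aucs[top] > best_auc + epsilon
    rows[[step]] <- data.frame(step = step, candidate = remaining[top],
                               auc = aucs[top], accepted = improved,
                               stringsAsFactors = FALSE)
    if (!improved) break
    selected <- c(selected, remaining[top])
    best_auc <- aucs[top]
  }
  list(selected = selected, trace = do.call(rbind, rows))
}
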