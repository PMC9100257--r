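# ---------------------------------------------------------------------------
# Phase-branched bi-directional LSTM regressor.
#
# Each gait phase has an independent branch of two stacked Bi-LSTM layers
# {64, 32} consuming that phase's selected features; the four per-frame
# branch outputs (width 2 x 32 each) are re-concatenated in phase order into
# one 100-frame sequence, passed through a combined trunk of two Bi-LSTM
# layers {32, 32}, and mapped per frame to the 3-axis CG by an affine head
# with sigmoid activation (outputs live in [0, 1], the min-max normalized
# target scale). Training: MSE loss, Adam (lr 0.001, batch 10, epoch cap
# 1000), learning-rate reduction on validation plateau, early stopping with
# best-weight restoration. The recurrent kernels (forward and
# backpropagation through time, with right-padding masks for the variable
# phase lengths) are implemented in compiled code.
# ---------------------------------------------------------------------------

#' Build a phase-branched Bi-LSTM model specification
#'
#' @param feature_counts integer vector: input feature count of each branch
#'   (one per gait phase; a single count gives the unbranched whole-cycle
#'   architecture used by the comparative baselines).
#' @param hidden_branch hidden sizes of the two stacked branch Bi-LSTM
#'   layers (default `c(64, 32)`).
#' @param hidden_trunk hidden sizes of the two combined trunk layers
#'   (default `c(32, 32)`).
#' @param n_outputs output channels per frame (default 3 CG axes).
#' @return a `cg_model_spec`.
#' @export
build_cg_model <- function(feature_counts, hidden_branch = c(64, 32),
                           hidden_trunk = c(32, 32), n_outputs = 3) {
  feature_counts <- as.integer(feature_counts)
  if (any(feature_counts < 1)) stop("every branch needs at least one feature")
  structure(list(feature_counts = feature_counts,
                 n_branches = length(feature_counts),
                 hidden_branch = as.integer(hidden_branch),
                 hidden_trunk = as.integer(hidden_trunk),
                 n_outputs = as.integer(n_outputs)),
            class = "cg_model_spec")
}

# --- parameter initialization ----------------------------------------------

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

lstm_param_init <- function(input_size, hidden) {
  b <- rep(0, 4 * hidden)
  b[(hidden + 1):(2 * hidden)] <- 1        # forget-gate bias
  list(W = glorot(4 * hidden, input_size), U = glorot(4 * hidden, hidden),
       b = b)
}

init_cg_params <- function(spec, seed = 1L) {
  set.seed(as.integer(seed))
  params <- list()
  for (p in seq_len(spec$n_branches)) {
    inp <- spec$feature_counts[p]
    for (l in seq_along(spec$hidden_branch)) {
      h <- spec$hidden_branch[l]
      for (d in c("f", "b")) {
        prm <- lstm_param_init(inp, h)
        for (nm in names(prm))
          params[[sprintf("br%d.l%d.%s.%s", p, l, d, nm)]] <- prm[[nm]]
      }
      inp <- 2 * h
    }
  }
  inp <- 2 * tail(spec$hidden_branch, 1)
  for (l in seq_along(spec$hidden_trunk)) {
    h <- spec$hidden_trunk[l]
    for (d in c("f", "b")) {
      prm <- lstm_param_init(inp, h)
      for (nm in names(prm))
        params[[sprintf("tr.l%d.%s.%s", l, d, nm)]] <- prm[[nm]]
    }
    inp <- 2 * h
  }
  params[["head.W"]] <- glorot(spec$n_outputs, inp)
  params[["head.b"]] <- rep(0, spec$n_outputs)
  params
}

# --- bi-directional layer wrappers ------------------------------------------

bilstm_forward <- function(X, mask, prm) {
  Tn <- dim(X)[3]
  ff <- .lstm_forward(X, mask, prm$f$W, prm$f$U, prm$f$b, FALSE)
  fb <- .lstm_forward(X, mask, prm$b$W, prm$b$U, prm$b$b, TRUE)
  H <- dim(ff$H)[1]
  B <- dim(X)[2]
  out <- array(0, c(2 * H, B, Tn))
  out[1:H, , ] <- ff$H
  out[(H + 1):(2 * H), , ] <- fb$H
  list(H = out, cache_f = ff, cache_b = fb)
}

bilstm_backward <- function(X, mask, prm, fwd, dH2) {
  H <- dim(fwd$cache_f$H)[1]
  dHf <- dH2[1:H, , , drop = FALSE]
  dHb <- dH2[(H + 1):(2 * H), , , drop = FALSE]
  bf <- .lstm_backward(X, mask, prm$f$W, prm$f$U, fwd$cache_f, dHf, FALSE)
  bb <- .lstm_backward(X, mask, prm$b$W, prm$b$U, fwd$cache_b, dHb, TRUE)
  list(dX = bf$dX + bb$dX,
       grads = list(f = list(W = bf$dW, U = bf$dU, b = as.vector(bf$db)),
                    b = list(W = bb$dW, U = bb$dU, b = as.vector(bb$db))))
}

get_prm <- function(params, prefix) {
  list(f = list(W = params[[paste0(prefix, ".f.W")]],
                U = params[[paste0(prefix, ".f.U")]],
                b = params[[paste0(prefix, ".f.b")]]),
       b = list(W = params[[paste0(prefix, ".b.W")]],
                U = params[[paste0(prefix, ".b.U")]],
                b = params[[paste0(prefix, ".b.b")]]))
}

put_grads <- function(grads, prefix, g) {
  for (d in c("f", "b"))
    for (nm in c("W", "U", "b")) {
      key <- sprintf("%s.%s.%s", prefix, d, nm)
      grads[[key]] <- if (is.null(grads[[key]])) g[[d]][[nm]] else
        grads[[key]] + g[[d]][[nm]]
    }
  grads
}

# --- full network forward / backward ----------------------------------------

# batch: list of samples; each sample has `branches` (list of T_p x k_p
# matrices, one per phase, lengths summing to n_frames) and optionally `y`
# (n_frames x n_outputs, normalized scale).
cg_forward <- function(params, spec, batch, n_frames = 100) {
  B <- length(batch)
  P <- spec$n_branches
  width <- 2 * tail(spec$hidden_branch, 1)
  trunk_in <- array(0, c(width, B, n_frames))
  cache <- list(branches = vector("list", P))
  offsets <- matrix(0L, B, P + 1)
  for (b in seq_len(B))
    offsets[b, ] <- cumsum(c(0L, vapply(batch[[b]]$branches, nrow, integer(1))))

  for (p in seq_len(P)) {
    lens <- vapply(batch, function(s) nrow(s$branches[[p]]), integer(1))
    Tmax <- max(lens)
    k <- spec$feature_counts[p]
    X <- array(0, c(k, B, Tmax))
    mask <- matrix(0, B, Tmax)
    for (b in seq_len(B)) {
      if (lens[b] > 0) {
        X[, b, seq_len(lens[b])] <- t(batch[[b]]$branches[[p]])
        mask[b, seq_len(lens[b])] <- 1
      }
    }
    f1 <- bilstm_forward(X, mask, get_prm(params, sprintf("br%d.l1", p)))
    f2 <- bilstm_forward(f1$H, mask, get_prm(params, sprintf("br%d.l2", p)))
    for (b in seq_len(B)) {
      if (lens[b] > 0)
        trunk_in[, b, (offsets[b, p] + 1):offsets[b, p + 1]] <-
          f2$H[, b, seq_len(lens[b])]
    }
    cache$branches[[p]] <- list(X = X, mask = mask, f1 = f1, f2 = f2,
                                lens = lens)
  }

  full_mask <- matrix(1, B, n_frames)
  t1 <- bilstm_forward(trunk_in, full_mask, get_prm(params, "tr.l1"))
  t2 <- bilstm_forward(t1$H, full_mask, get_prm(params, "tr.l2"))

  Hlast <- matrix(t2$H, nrow = dim(t2$H)[1])          # (width, B*T)
  Z <- params[["head.W"]] %*% Hlast + params[["head.b"]]
  Y <- 1 / (1 + exp(-Z))                              # (n_outputs, B*T)

  cache$trunk_in <- trunk_in
  cache$full_mask <- full_mask
  cache$t1 <- t1
  cache$t2 <- t2
  cache$Hlast <- Hlast
  cache$Y <- Y
  cache$offsets <- offsets
  # per-sample predictions as n_frames x n_outputs matrices
  preds <- lapply(seq_len(B), function(b) {
    t(Y[, seq(b, B * n_frames, by = B), drop = FALSE])
  })
  list(preds = preds, cache = cache)
}

cg_backward <- function(params, spec, batch, fw, n_frames = 100) {
  B <- length(batch)
  P <- spec$n_branches
  cache <- fw$cache
  Y <- cache$Y
  # MSE gradient on the normalized scale
  Ytar <- matrix(0, nrow = spec$n_outputs, ncol = B * n_frames)
  for (b in seq_len(B))
    Ytar[, seq(b, B * n_frames, by = B)] <- t(batch[[b]]$y)
  dY <- 2 * (Y - Ytar) / length(Y)
  dZ <- dY * Y * (1 - Y)

  grads <- list()
  grads[["head.W"]] <- dZ %*% t(cache$Hlast)
  grads[["head.b"]] <- rowSums(dZ)
  dHlast <- t(params[["head.W"]]) %*% dZ
  dH2 <- array(dHlast, dim(cache$t2$H))

  bt2 <- bilstm_backward(cache$t1$H, cache$full_mask, get_prm(params, "tr.l2"),
                         cache$t2, dH2)
  grads <- put_grads(grads, "tr.l2", bt2$grads)
  bt1 <- bilstm_backward(cache$trunk_in, cache$full_mask,
                         get_prm(params, "tr.l1"), cache$t1, bt2$dX)
  grads <- put_grads(grads, "tr.l1", bt1$grads)

  for (p in seq_len(P)) {
    bc <- cache$branches[[p]]
    Tmax <- dim(bc$X)[3]
    dOut <- array(0, dim(bc$f2$H))
    for (b in seq_len(B)) {
      if (bc$lens[b] > 0)
        dOut[, b, seq_len(bc$lens[b])] <-
          bt1$dX[, b, (cache$offsets[b, p] + 1):cache$offsets[b, p + 1]]
    }
    b2 <- bilstm_backward(bc$f1$H, bc$mask, get_prm(params, sprintf("br%d.l2", p)),
                          bc$f2, dOut)
    grads <- put_grads(grads, sprintf("br%d.l2", p), b2$grads)
    b1 <- bilstm_backward(bc$X, bc$mask, get_prm(params, sprintf("br%d.l1", p)),
                          bc$f1, b2$dX)
    grads <- put_grads(grads, sprintf("br%d.l1", p), b1$grads)
  }
  grads
}

cg_batch_loss <- function(preds, batch) {
  se <- 0; nv <- 0
  for (b in seq_along(batch)) {
    se <- se + sum((preds[[b]] - batch[[b]]$y)^2)
    nv <- nv + length(batch[[b]]$y)
  }
  se / nv
}

# --- min-max normalization ---------------------------------------------------

#' Min-max normalization to [0, 1] with stored constants
#'
#' Per-column `(x - min) / (max - min)` using constants derived from the
#' training data only. Constant (zero-range) columns are flagged and mapped
#' to 0. Values outside the training range map outside `[0, 1]` (no
#' clipping); the inverse transform is exact.
#'
#' @param x numeric matrix (rows = observations / frames).
#' @param constants optional list with `min` and `max` per column (training
#'   constants); computed from `x` when omitted.
#' @return list with `x` (normalized) and `constants` (`min`, `max`,
#'   `constant` flag per column).
#' @export
minmax_normalize <- function(x, constants = NULL) {
  x <- as.matrix(x)
  if (is.null(constants)) {
    mn <- apply(x, 2, min)
    mx <- apply(x, 2, max)
    constants <- list(min = mn, max = mx, constant = mx - mn <= 0)
  }
  rng <- constants$max - constants$min
  rng[constants$constant] <- 1
  out <- sweep(sweep(x, 2, constants$min), 2, rng, "/")
  out[, constants$constant] <- 0
  list(x = out, constants = constants)
}

#' @rdname minmax_normalize
#' @param xn normalized matrix.
#' @export
minmax_denormalize <- function(xn, constants) {
  rng <- constants$max - constants$min
  rng[constants$constant] <- 0
  sweep(sweep(as.matrix(xn), 2, rng, "*"), 2, constants$min, "+")
}

# --- Adam --------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip_norm = 5) {
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  scale <- if (gnorm > clip_norm) clip_norm / gnorm else 1
  state$t <- state$t + 1
  bc1 <- 1 - 0.9^state$t
  bc2 <- 1 - 0.999^state$t
  for (nm in names(params)) {
    g <- grads[[nm]] * scale
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# --- training loop -----------------------------------------------------------

#' Train the phase-branched Bi-LSTM CG regressor
#'
#' Minimizes the mean squared error on the min-max normalized targets with
#' Adam (defaults: batch size 10, initial learning rate 0.001, epoch cap
#' 1000), reducing the learning rate on a validation-loss plateau and
#' stopping early when validation loss no longer improves; the best-epoch
#' weights are restored. Deterministic given `seed` (single-threaded BLAS).
#'
#' @param samples_train,samples_val lists of prepared samples (see
#'   [prepare_cg_samples()]); validation subjects must be disjoint from
#'   training subjects.
#' @param spec a [build_cg_model()] specification.
#' @param seed RNG seed for initialization and shuffling.
#' @param epochs epoch cap (default 1000).
#' @param batch_size minibatch size (default 10).
#' @param lr initial learning rate (default 0.001).
#' @param plateau_patience,plateau_factor,min_lr learning-rate reduction on
#'   validation plateau (defaults: patience 20, factor 0.5, floor 1e-5).
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (default 50).
#' @param clip_norm global gradient-norm clip.
#' @param verbose print per-epoch losses.
#' @return list with `params`, `spec`, `history` (data.frame epoch /
#'   train_loss / val_loss / lr), `best_epoch`, `stop_epoch`.
#' @export
train_cg_network <- function(samples_train, samples_val, spec, seed = 1L,
                             epochs = 1000, batch_size = 10, lr = 0.001,
                             plateau_patience = 20, plateau_factor = 0.5,
                             min_lr = 1e-5, early_stop_patience = 50,
                             clip_norm = 5, verbose = FALSE) {
  params <- init_cg_params(spec, seed = seed)
  state <- adam_init(params)
  set.seed(as.integer(seed) + 1L)
  n <- length(samples_train)
  history <- NULL
  best_val <- Inf; best_params <- params; best_epoch <- 0L
  since_improve <- 0L; since_plateau <- 0L
  cur_lr <- lr

  val_loss <- function(prm) {
    tot <- 0; cnt <- 0
    i <- 1
    while (i <= length(samples_val)) {
      j <- min(i + batch_size - 1, length(samples_val))
      bt <- samples_val[i:j]
      fw <- cg_forward(prm, spec, bt)
      tot <- tot + cg_batch_loss(fw$preds, bt) * length(bt)
      cnt <- cnt + length(bt)
      i <- j + 1
    }
    tot / cnt
  }

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tr_tot <- 0; tr_cnt <- 0
    i <- 1
    while (i <= n) {
      j <- min(i + batch_size - 1, n)
      bt <- samples_train[ord[i:j]]
      fw <- cg_forward(params, spec, bt)
      if (!all(is.finite(fw$cache$Y)))
        stop("training diverged: non-finite network output at epoch ", ep)
      tr_tot <- tr_tot + cg_batch_loss(fw$preds, bt) * length(bt)
      tr_cnt <- tr_cnt + length(bt)
      grads <- cg_backward(params, spec, bt, fw)
      upd <- adam_step(params, grads, state, cur_lr, clip_norm = clip_norm)
      params <- upd$params
      state <- upd$state
      i <- j + 1
    }
    vl <- val_loss(params)
    history <- rbind(history, data.frame(epoch = ep, train_loss = tr_tot / tr_cnt,
                                         val_loss = vl, lr = cur_lr))
    if (verbose)
      message(sprintf("epoch %d train %.6f val %.6f lr %.2g", ep,
                      tr_tot / tr_cnt, vl, cur_lr))
    if (vl < best_val - 1e-9) {
      best_val <- vl; best_params <- params; best_epoch <- ep
      since_improve <- 0L; since_plateau <- 0L
    } else {
      since_improve <- since_improve + 1L
      since_plateau <- since_plateau + 1L
    }
    if (since_plateau >= plateau_patience && cur_lr > min_lr) {
      cur_lr <- max(cur_lr * plateau_factor, min_lr)
      since_plateau <- 0L
    }
    if (since_improve >= early_stop_patience) break
  }
  list(params = best_params, spec = spec, history = history,
       best_epoch = best_epoch, stop_epoch = nrow(history))
}

# --- data preparation and the high-level model object ------------------------

#' Prepare cycles as network samples
#'
#' Extracts the 240 windowed feature candidates from each cycle's parameter
#' series, slices them per phase into the chosen per-phase feature columns,
#' and min-max normalizes inputs and targets (constants computed from these
#' samples when not supplied, i.e. from the training set).
#'
#' @param cycles list of cycles: each a list with `x` (frames x 30 parameter
#'   matrix), `y` (frames x 3 CG targets, leg-length-normalized), `phases`
#'   (integer labels).
#' @param chosen list (one entry per phase, in phase order) of feature-name
#'   vectors selecting each branch's inputs.
#' @param norm optional normalization constants from a previous call.
#' @param window feature window length.
#' @return list with `samples` (each: `branches`, `y`) and `norm`
#'   (`input` constants per phase, `target` constants).
#' @export
prepare_cg_samples <- function(cycles, chosen, norm = NULL, window = 5) {
  P <- length(chosen)
  feats <- lapply(cycles, function(cyc) extract_window_features(cyc$x, window))
  cols <- lapply(chosen, function(ch) {
    if (is.character(ch)) match(ch, colnames(feats[[1]])) else ch
  })
  if (anyNA(unlist(cols))) stop("chosen feature names not found")

  raw_samples <- lapply(seq_along(cycles), function(i) {
    cyc <- cycles[[i]]
    branches <- lapply(seq_len(P), function(p) {
      rows <- if (P == 1) seq_len(nrow(feats[[i]])) else which(cyc$phases == p)
      feats[[i]][rows, cols[[p]], drop = FALSE]
    })
    list(branches = branches, y = as.matrix(cyc$y))
  })

  if (is.null(norm)) {
    norm <- list(input = lapply(seq_len(P), function(p) {
      pooled <- do.call(rbind, lapply(raw_samples, function(s) s$branches[[p]]))
      minmax_normalize(pooled)$constants
    }), target = minmax_normalize(do.call(rbind, lapply(raw_samples,
                                                        function(s) s$y)))$constants)
  }
  samples <- lapply(raw_samples, function(s) {
    s$branches <- lapply(seq_len(P), function(p)
      minmax_normalize(s$branches[[p]], norm$input[[p]])$x)
    s$y <- minmax_normalize(s$y, norm$target)$x
    s
  })
  list(samples = samples, norm = norm)
}

#' Fit the CG trajectory model on training cycles
#'
#' High-level wrapper: prepares the samples (feature extraction, per-phase
#' slicing, min-max normalization with training-set constants), builds the
#' network specification from the per-phase feature counts, and trains it.
#'
#' @param train_cycles,val_cycles cycle lists (see [prepare_cg_samples()]);
#'   disjoint at subject level.
#' @param chosen per-phase chosen feature names (length 1 for the unbranched
#'   whole-cycle baseline).
#' @param seed RNG seed.
#' @param ... passed to [train_cg_network()] (e.g. `epochs`).
#' @return a `trained_cg_model`: list with `network` (params + history),
#'   `chosen`, `norm`, `spec`.
#' @export
fit_cg_model <- function(train_cycles, val_cycles, chosen, seed = 1L, ...) {
  ptr <- prepare_cg_samples(train_cycles, chosen)
  pva <- prepare_cg_samples(val_cycles, chosen, norm = ptr$norm)
  spec <- build_cg_model(vapply(chosen, length, integer(1)))
  net <- train_cg_network(ptr$samples, pva$samples, spec, seed = seed, ...)
  structure(list(network = net, chosen = chosen, norm = ptr$norm, spec = spec),
            class = "trained_cg_model")
}

#' Predict the CG trajectory of a cycle
#'
#' @param object a `trained_cg_model`.
#' @param cycle a cycle list with `x` (frames x 30 parameters) and `phases`.
#' @param leg_length optional leg length (mm) to also return the trajectory
#'   in mm as the `"raw_mm"` attribute.
#' @param ... unused.
#' @return frames x 3 matrix in leg-length-normalized units (attribute
#'   `raw_mm` in mm when `leg_length` is given).
#' @export
predict.trained_cg_model <- function(object, cycle, leg_length = NULL, ...) {
  cyc <- cycle
  cyc$y <- matrix(0, nrow = nrow(cyc$x), ncol = object$spec$n_outputs)
  prep <- prepare_cg_samples(list(cyc), object$chosen, norm = object$norm)
  fw <- cg_forward(object$network$params, object$spec, prep$samples,
                   n_frames = nrow(cyc$x))
  out <- minmax_denormalize(fw$preds[[1]], object$norm$target)
  colnames(out) <- c("ap", "ml", "pd")
  if (!is.null(leg_length)) attr(out, "raw_mm") <- out * leg_length
  out
}

#' Save / load a trained CG model archive
#'
#' Weights, per-phase feature lists, normalization constants and training
#' history in one versioned archive.
#'
#' @param model a `trained_cg_model`.
#' @param path archive path.
#' @export
save_cg_model <- function(model, path) {
  saveRDS(list(format_version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_cg_model
#' @export
load_cg_model <- function(path) {
  arc <- readRDS(path)
  if (is.null(arc$format_version)) stop("not a CG model archive")
  arc$model
}
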