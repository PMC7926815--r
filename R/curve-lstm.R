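# Sequence-to-point LSTM regressors for per-sample vGRF (xBW) and binary
# ground-contact labels of both feet, from raw 6-channel sensor input
# (3D acceleration + 3D angular rate).
#
# Architecture: LSTM -> additive zero-mean Gaussian input noise (training
# only) -> LSTM -> dropout (training only) -> fully connected 2-unit output;
# ReLU output and mean-squared-error loss for the vgrf task, sigmoid output
# and binary cross-entropy for the gct task; adam optimizer. The network is
# implemented natively with batched matrix operations and hand-derived
# backpropagation-through-time gradients (verified against numerical
# differentiation in the test suite).

#' Min-max scale sensor channels to [-1, 1]
#'
#' Training mode computes per-channel minima/maxima and maps them to -1 and
#' +1; inference mode reuses stored statistics (so values outside the
#' training range may exceed [-1, 1]). A constant channel maps to all zeros.
#'
#' @param x numeric matrix, samples x channels
#' @param stats optional statistics from a previous call (inference mode)
#' @return list with `scaled` (matrix) and `stats` (list of `min`, `max`)
#' @export
scale_channels <- function(x, stats = NULL) {
  x <- as.matrix(x)
  if (!nrow(x)) stopf("empty channel matrix")
  if (is.null(stats))
    stats <- list(min = apply(x, 2, min), max = apply(x, 2, max))
  rng <- stats$max - stats$min
  scaled <- vapply(seq_len(ncol(x)), function(j) {
    if (rng[j] == 0) rep(0, nrow(x))
    else 2 * (x[, j] - stats$min[j]) / rng[j] - 1
  }, numeric(nrow(x)))
  list(scaled = matrix(scaled, nrow = nrow(x),
                       dimnames = list(NULL, colnames(x))),
       stats = stats)
}

#' Invert [scale_channels()]
#' @param scaled scaled matrix
#' @param stats statistics returned by [scale_channels()]
#' @export
unscale_channels <- function(scaled, stats) {
  rng <- stats$max - stats$min
  out <- vapply(seq_len(ncol(scaled)), function(j) {
    if (rng[j] == 0) rep(stats$min[j], nrow(scaled))
    else (scaled[, j] + 1) / 2 * rng[j] + stats$min[j]
  }, numeric(nrow(scaled)))
  matrix(out, nrow = nrow(scaled), dimnames = dimnames(scaled))
}

#' Sliding-window sequence dataset
#'
#' Windows of `window` consecutive samples shifted by one sample; the target
#' of a window is the label/force at its final sample, so a trace of length
#' `n` yields `n - window + 1` windows (no predictions exist for the first
#' `window - 1` samples). Windows are materialized lazily at batch time.
#'
#' @param x scaled input matrix, samples x channels
#' @param y target matrix, samples x 2 (left/right force in xBW, or
#'   contact labels in 0/1)
#' @param window window length in samples (default 400, one mean stride at
#'   400 Hz)
#' @return object of class `sequence_dataset` with element `n_windows`
#' @export
make_sequences <- function(x, y, window = 400L) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) < window)
    stopf("too short: %d samples < window of %d", nrow(x), window)
  if (nrow(y) != nrow(x)) stopf("inputs and targets must be aligned")
  if (ncol(y) != 2L) stopf("targets must have 2 columns (left, right)")
  structure(list(x = x, y = y, window = as.integer(window),
                 n_windows = nrow(x) - as.integer(window) + 1L),
            class = "sequence_dataset")
}

#' LSTM model specification
#'
#' @param task `"vgrf"` (ReLU output, MSE loss) or `"gct"` (sigmoid output,
#'   binary cross-entropy loss)
#' @param hidden sizes of the two LSTM layers
#' @param dropout dropout rate after the second LSTM layer (training only)
#' @param noise_sd SD of the additive Gaussian noise between the LSTM layers
#'   (training only)
#' @param epochs training epochs
#' @param batch_size minibatch size
#' @param lr adam learning rate
#' @param window window length in samples
#' @param seed integer RNG seed
#' @export
lstm_spec <- function(task = c("vgrf", "gct"), hidden = c(64L, 64L),
                      dropout = 0.2, noise_sd = 0.05, epochs = 10L,
                      batch_size = 256L, lr = 3e-3, window = 400L, seed = 1L) {
  task <- match.arg(task)
  stopifnot(length(hidden) == 2L, all(hidden >= 1L), dropout >= 0, dropout < 1,
            noise_sd >= 0, epochs >= 1L, batch_size >= 1L, window >= 2L)
  structure(list(task = task, hidden = as.integer(hidden), dropout = dropout,
                 noise_sd = noise_sd, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 window = as.integer(window), seed = as.integer(seed)),
            class = "lstm_spec")
}

# ---- parameter handling ------------------------------------------------------

lstm_init_params <- function(n_in, spec) {
  H1 <- spec$hidden[1L]; H2 <- spec$hidden[2L]
  glorot <- function(nr, nc) {
    r <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -r, r), nr, nc)
  }
  gate_bias <- function(H) {         # forget-gate bias starts at +1
    b <- numeric(4L * H); b[(H + 1L):(2L * H)] <- 1; b
  }
  list(Wx1 = glorot(n_in, 4L * H1), Wh1 = glorot(H1, 4L * H1), b1 = gate_bias(H1),
       Wx2 = glorot(H1, 4L * H2), Wh2 = glorot(H2, 4L * H2), b2 = gate_bias(H2),
       W3 = glorot(H2, 2L), b3 = numeric(2L))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# One LSTM layer forward over T steps. xs: list of T input matrices (B x C).
# Returns final h plus per-step caches needed for BPTT.
lstm_layer_forward <- function(xs, Wx, Wh, b, cache = TRUE) {
  T_ <- length(xs); B <- nrow(xs[[1L]]); H <- nrow(Wh)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  gates <- if (cache) vector("list", T_) else NULL
  cs <- if (cache) vector("list", T_) else NULL
  hs <- if (cache) vector("list", T_) else NULL
  for (t in seq_len(T_)) {
    Z <- xs[[t]] %*% Wx + h %*% Wh + rep(b, each = B)
    i <- sigmoid(Z[, 1:H, drop = FALSE])
    f <- sigmoid(Z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(Z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(Z[, (3 * H + 1):(4 * H), drop = FALSE])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    if (cache) {
      gates[[t]] <- list(i = i, f = f, g = g, o = o)
      cs[[t]] <- cc; hs[[t]] <- h
    }
  }
  list(h = h, gates = gates, cs = cs, hs = hs)
}

# BPTT through one LSTM layer. dh_steps: list of per-step external gradients
# on h (or NULL), dh_final: gradient on the last h. Returns parameter
# gradients and per-step gradients w.r.t. the inputs.
lstm_layer_backward <- function(xs, fw, Wx, Wh, dh_final, dh_steps = NULL) {
  T_ <- length(xs); B <- nrow(xs[[1L]]); H <- nrow(Wh)
  dWx <- matrix(0, nrow(Wx), ncol(Wx)); dWh <- matrix(0, H, 4L * H)
  db <- numeric(4L * H)
  dxs <- vector("list", T_)
  dh <- dh_final
  dc <- matrix(0, B, H)
  for (t in rev(seq_len(T_))) {
    if (!is.null(dh_steps) && t < T_) dh <- dh + dh_steps[[t]]
    gt <- fw$gates[[t]]
    tc <- tanh(fw$cs[[t]])
    do_ <- dh * tc
    dc <- dc + dh * gt$o * (1 - tc^2)
    c_prev <- if (t > 1L) fw$cs[[t - 1L]] else matrix(0, B, H)
    di <- dc * gt$g; df <- dc * c_prev; dg <- dc * gt$i
    dc <- dc * gt$f
    dZ <- cbind(di * gt$i * (1 - gt$i), df * gt$f * (1 - gt$f),
                dg * (1 - gt$g^2), do_ * gt$o * (1 - gt$o))
    h_prev <- if (t > 1L) fw$hs[[t - 1L]] else matrix(0, B, H)
    dWx <- dWx + crossprod(xs[[t]], dZ)
    dWh <- dWh + crossprod(h_prev, dZ)
    db <- db + colSums(dZ)
    dxs[[t]] <- dZ %*% t(Wx)
    dh <- dZ %*% t(Wh)
  }
  list(dWx = dWx, dWh = dWh, db = db, dxs = dxs)
}

# Full-network forward (and optionally backward) pass for one batch of
# windows. xs: list of T input matrices. Returns predictions, loss, grads.
lstm_batch <- function(params, spec, xs, y = NULL, training = FALSE,
                       want_grads = FALSE) {
  B <- nrow(xs[[1L]]); T_ <- length(xs); H2 <- spec$hidden[2L]
  # layer 1 always caches its per-step outputs: they are layer 2's inputs
  fw1 <- lstm_layer_forward(xs, params$Wx1, params$Wh1, params$b1,
                            cache = TRUE)
  xs2 <- fw1$hs
  if (training && spec$noise_sd > 0) {
    xs2 <- lapply(xs2, function(h)
      h + matrix(stats::rnorm(length(h), 0, spec$noise_sd), nrow(h)))
  }
  fw2 <- lstm_layer_forward(xs2, params$Wx2, params$Wh2, params$b2,
                            cache = want_grads)
  h2 <- fw2$h
  dropmask <- NULL
  if (training && spec$dropout > 0) {
    dropmask <- matrix(stats::rbinom(B * H2, 1L, 1 - spec$dropout),
                       B, H2) / (1 - spec$dropout)
    h2 <- h2 * dropmask
  }
  z3 <- h2 %*% params$W3 + rep(params$b3, each = B)
  pred <- if (spec$task == "vgrf") pmax(z3, 0) else sigmoid(z3)
  loss <- NULL
  if (!is.null(y)) {
    loss <- if (spec$task == "vgrf") {
      mean((pred - y)^2)
    } else {
      p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
      -mean(y * log(p) + (1 - y) * log(1 - p))
    }
  }
  if (!want_grads)
    return(list(pred = pred, loss = loss))

  dz3 <- if (spec$task == "vgrf") {
    2 * (pred - y) * (z3 > 0) / length(y)
  } else {
    (pred - y) / length(y)
  }
  dW3 <- crossprod(h2, dz3)
  db3 <- colSums(dz3)
  dh2 <- dz3 %*% t(params$W3)
  if (!is.null(dropmask)) dh2 <- dh2 * dropmask
  bk2 <- lstm_layer_backward(xs2, fw2, params$Wx2, params$Wh2, dh2)
  # noise layer passes gradients through to layer-1 outputs at every step
  bk1 <- lstm_layer_backward(xs, fw1, params$Wx1, params$Wh1,
                             dh_final = bk2$dxs[[T_]],
                             dh_steps = bk2$dxs)
  list(pred = pred, loss = loss,
       grads = list(Wx1 = bk1$dWx, Wh1 = bk1$dWh, b1 = bk1$db,
                    Wx2 = bk2$dWx, Wh2 = bk2$dWh, b2 = bk2$db,
                    W3 = dW3, b3 = db3))
}

# windows -> list of T batch matrices for window start indices `starts`
batch_windows <- function(x, starts, window) {
  lapply(seq_len(window), function(t) x[starts + t - 1L, , drop = FALSE])
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train an LSTM curve model
#'
#' Minibatch adam training of the two-layer LSTM on a sliding-window
#' dataset. Training is deterministic for a fixed spec seed. The returned
#' model records the loss history; training fails with a diagnostic error if
#' the loss becomes non-finite.
#'
#' @param dataset a [make_sequences()] dataset
#' @param spec an [lstm_spec()]
#' @return object of class `lstm_model` (parameters, spec, loss history)
#' @export
train_curve_model <- function(dataset, spec) {
  stopifnot(inherits(dataset, "sequence_dataset"), inherits(spec, "lstm_spec"))
  if (dataset$window != spec$window)
    stopf("dataset window (%d) differs from spec window (%d)",
          dataset$window, spec$window)
  set.seed(spec$seed)
  params <- lstm_init_params(ncol(dataset$x), spec)
  state <- list(t = 0L,
                m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  n_w <- dataset$n_windows
  eval_starts <- seq_len(min(512L, n_w))
  eval_xs <- batch_windows(dataset$x, eval_starts, dataset$window)
  eval_y <- dataset$y[eval_starts + dataset$window - 1L, , drop = FALSE]
  loss0 <- lstm_batch(params, spec, eval_xs, eval_y)$loss
  losses <- numeric(spec$epochs)
  for (ep in seq_len(spec$epochs)) {
    ord <- sample.int(n_w)
    ep_loss <- 0; n_b <- 0L
    for (b0 in seq(1L, n_w, by = spec$batch_size)) {
      starts <- ord[b0:min(b0 + spec$batch_size - 1L, n_w)]
      xs <- batch_windows(dataset$x, starts, dataset$window)
      y <- dataset$y[starts + dataset$window - 1L, , drop = FALSE]
      res <- lstm_batch(params, spec, xs, y, training = TRUE,
                        want_grads = TRUE)
      if (!is.finite(res$loss))
        stopf("training failure: non-finite loss at epoch %d (lr too high?)", ep)
      upd <- adam_step(params, res$grads, state, spec$lr)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + res$loss; n_b <- n_b + 1L
    }
    losses[ep] <- ep_loss / n_b
  }
  loss1 <- lstm_batch(params, spec, eval_xs, eval_y)$loss
  structure(list(params = params, spec = spec, n_inputs = ncol(dataset$x),
                 loss_initial = loss0, loss_final = loss1,
                 epoch_losses = losses),
            class = "lstm_model")
}

#' @export
print.lstm_model <- function(x, ...) {
  cat(sprintf("<lstm_model> task=%s hidden=%d/%d window=%d; loss %0.4g -> %0.4g over %d epochs\n",
              x$spec$task, x$spec$hidden[1L], x$spec$hidden[2L], x$spec$window,
              x$loss_initial, x$loss_final, x$spec$epochs))
  invisible(x)
}

#' Forward pass of an LSTM model on a batch of windows
#'
#' Exposed mainly for diagnostics: in training mode the noise and dropout
#' layers are active (stochastic output, advancing the RNG); in evaluation
#' mode the pass is deterministic.
#'
#' @param model an `lstm_model`
#' @param x scaled input matrix (samples x channels)
#' @param starts window start indices (1-based)
#' @param training activate noise/dropout
#' @return prediction matrix, length(starts) x 2
#' @export
lstm_forward <- function(model, x, starts, training = FALSE) {
  xs <- batch_windows(as.matrix(x), starts, model$spec$window)
  lstm_batch(model$params, model$spec, xs, training = training)$pred
}

#' Predict per-sample curves for a whole trace
#'
#' Slides the window over the scaled trace one sample at a time; predictions
#' start at the window's final sample, so the output has
#' `nrow(x) - window + 1` rows (both feet as columns). The vgrf task returns
#' forces in xBW, the gct task contact probabilities.
#'
#' @param model a trained `lstm_model`
#' @param x scaled input matrix (inference-mode [scale_channels()] output)
#' @param batch_size windows evaluated per forward pass
#' @return numeric matrix, `(nrow(x) - window + 1)` x 2
#' @export
predict_curves <- function(model, x, batch_size = 512L) {
  x <- as.matrix(x)
  w <- model$spec$window
  if (nrow(x) < w) stopf("too short: %d samples < window of %d", nrow(x), w)
  n_w <- nrow(x) - w + 1L
  out <- matrix(NA_real_, n_w, 2L)
  for (b0 in seq(1L, n_w, by = batch_size)) {
    starts <- b0:min(b0 + batch_size - 1L, n_w)
    out[starts, ] <- lstm_forward(model, x, starts, training = FALSE)
  }
  out
}

#' Threshold contact probabilities into binary labels
#'
#' Values below 0.5 become 0; 0.5 and above become 1.
#'
#' @param probabilities numeric values in [0, 1]
#' @return integer labels, same shape
#' @export
binarize_labels <- function(probabilities) {
  p <- probabilities
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stopf("probabilities must lie in [0, 1]")
  out <- ifelse(p >= 0.5, 1L, 0L)
  if (is.matrix(p)) matrix(out, nrow(p), dimnames = dimnames(p)) else out
}

#' Percentage agreement of binary label vectors
#' @param pred,truth equal-length binary vectors/matrices
#' @return accuracy in percent
#' @export
label_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth))
    stopf("label vectors differ in length (%d vs %d)", length(pred),
          length(truth))
  100 * mean(as.integer(pred) == as.integer(truth))
}
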