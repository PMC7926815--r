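# Channel scaling, sliding windows, LSTM training mechanics and gradients.

tiny_spec <- function(task = "vgrf", ...) {
  lstm_spec(task, hidden = c(3L, 2L), dropout = 0, noise_sd = 0,
            epochs = 2L, batch_size = 8L, window = 5L, seed = 2, ...)
}

test_that("channel scaling maps min/max to -1/1 and round-trips", {
  x <- cbind(a = c(0, 5, 10), b = c(2, 2, 2))
  sc <- scale_channels(x)
  expect_equal(sc$scaled[, "a"], c(-1, 0, 1))
  expect_equal(sc$scaled[, "b"], c(0, 0, 0))      # constant channel rule
  back <- unscale_channels(sc$scaled, sc$stats)
  expect_equal(back, x)
  # inference mode reuses stats and may exceed [-1, 1]
  sc2 <- scale_channels(cbind(a = 20, b = 2), sc$stats)
  expect_equal(unname(sc2$scaled[1, "a"]), 3)
})

test_that("window arithmetic follows the length-minus-window-plus-one law", {
  x <- matrix(rnorm(1000 * 2), ncol = 2)
  y <- matrix(0, 1000, 2)
  expect_identical(make_sequences(x, y, 400L)$n_windows, 601L)
  expect_identical(make_sequences(x[1:400, ], y[1:400, ], 400L)$n_windows, 1L)
  expect_error(make_sequences(x[1:399, ], y[1:399, ], 400L), "too short")
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(9)
  for (task in c("vgrf", "gct")) {
    spec <- tiny_spec(task)
    params <- gaitgrf:::lstm_init_params(4L, spec)
    B <- 3L
    xs <- lapply(1:5, function(t) matrix(rnorm(B * 4), B, 4))
    y <- if (task == "vgrf") matrix(abs(rnorm(B * 2)), B, 2) else
      matrix(rbinom(B * 2, 1, 0.5), B, 2)
    res <- gaitgrf:::lstm_batch(params, spec, xs, y, want_grads = TRUE)
    eps <- 1e-6
    for (nm in names(params)) {
      for (k in sample(length(params[[nm]]), min(5, length(params[[nm]])))) {
        pp <- params; pp[[nm]][k] <- pp[[nm]][k] + eps
        pm <- params; pm[[nm]][k] <- pm[[nm]][k] - eps
        num <- (gaitgrf:::lstm_batch(pp, spec, xs, y)$loss -
                  gaitgrf:::lstm_batch(pm, spec, xs, y)$loss) / (2 * eps)
        ana <- res$grads[[nm]][k]
        expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
      }
    }
  }
})

test_that("training decreases the loss and respects output activations", {
  set.seed(31)
  n <- 120L
  x <- cbind(sin(1:n / 3), cos(1:n / 5))
  y <- cbind(pmax(sin(1:n / 3), 0), pmax(cos(1:n / 5), 0))
  sc <- scale_channels(x)
  ds <- make_sequences(sc$scaled, y, window = 5L)
  spec <- lstm_spec("vgrf", hidden = c(6L, 6L), dropout = 0, noise_sd = 0,
                    epochs = 4L, batch_size = 16L, window = 5L, seed = 3)
  m <- train_curve_model(ds, spec)
  expect_lt(m$loss_final, m$loss_initial)
  p <- predict_curves(m, sc$scaled)
  expect_identical(nrow(p), n - 4L)
  expect_true(all(p >= 0))                       # ReLU output
  # gct task: sigmoid outputs in (0, 1)
  yb <- cbind(as.integer(y[, 1] > 0), as.integer(y[, 2] > 0))
  mb <- train_curve_model(make_sequences(sc$scaled, yb, 5L),
                          lstm_spec("gct", hidden = c(6L, 6L), dropout = 0,
                                    noise_sd = 0, epochs = 2L,
                                    batch_size = 16L, window = 5L, seed = 4))
  pb <- predict_curves(mb, sc$scaled)
  expect_true(all(pb > 0 & pb < 1))
})

test_that("an untrained model still returns finite, correctly shaped output", {
  set.seed(6)
  spec <- tiny_spec()
  params <- gaitgrf:::lstm_init_params(3L, spec)
  m <- structure(list(params = params, spec = spec, n_inputs = 3L),
                 class = "lstm_model")
  x <- matrix(rnorm(50 * 3), 50, 3)
  p <- predict_curves(m, x)
  expect_identical(dim(p), c(46L, 2L))
  expect_true(all(is.finite(p)))
})

test_that("noise and dropout act only in training mode", {
  set.seed(8)
  spec <- lstm_spec("vgrf", hidden = c(4L, 4L), dropout = 0.3, noise_sd = 0.1,
                    epochs = 1L, batch_size = 4L, window = 6L, seed = 5)
  params <- gaitgrf:::lstm_init_params(2L, spec)
  m <- structure(list(params = params, spec = spec, n_inputs = 2L),
                 class = "lstm_model")
  x <- matrix(rnorm(30 * 2), 30, 2)
  tr1 <- lstm_forward(m, x, starts = 1:4, training = TRUE)
  tr2 <- lstm_forward(m, x, starts = 1:4, training = TRUE)
  expect_false(isTRUE(all.equal(tr1, tr2)))      # stochastic layers active
  ev1 <- lstm_forward(m, x, starts = 1:4, training = FALSE)
  ev2 <- lstm_forward(m, x, starts = 1:4, training = FALSE)
  expect_identical(ev1, ev2)                     # deterministic in eval mode
})

test_that("label thresholding and accuracy follow their definitions", {
  expect_identical(binarize_labels(c(0.49, 0.5, 1.0, 0)), c(0L, 1L, 1L, 0L))
  expect_error(binarize_labels(c(0.2, 1.3)), "0, 1")
  expect_equal(label_accuracy(c(1, 0, 1), c(1, 0, 1)), 100)
  expect_equal(label_accuracy(c(1, 0), c(0, 1)), 0)
  expect_equal(label_accuracy(c(rep(1, 97), 0, 0, 0), rep(1, 100)), 97)
  expect_error(label_accuracy(1:3, 1:4), "length")
})

test_that("non-finite loss aborts training with a diagnostic", {
  set.seed(41)
  x <- matrix(rnorm(60 * 2), 60, 2)
  y <- matrix(rnorm(60 * 2) * 1e200, 60, 2)     # overflows the MSE
  ds <- make_sequences(scale_channels(x)$scaled, y, window = 5L)
  spec <- lstm_spec("vgrf", hidden = c(3L, 3L), dropout = 0, noise_sd = 0,
                    epochs = 1L, batch_size = 16L, window = 5L, seed = 1)
  expect_error(train_curve_model(ds, spec), "training failure")
})
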