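# KNN curve library: build, query (exhaustive vs kd-tree), assembly.

knn_fixture <- function() fixture("knn_lib", function() {
  s <- mixed_session()
  slices <- session_slices(s)
  tt <- s$truth$targets
  lib <- build_curve_library(slices, tt, s$strides$duration,
                             s$profile$body_weight)
  list(s = s, slices = slices, lib = lib, targets = tt)
})

test_that("the library stores one key and one curve per stride and foot", {
  kf <- knn_fixture()
  n <- nrow(kf$s$strides)
  expect_identical(nrow(kf$lib$left$curves), n)
  expect_identical(nrow(kf$lib$left$keys), n)
  expect_identical(nrow(kf$lib$right$curves), n)
  expect_identical(colnames(kf$lib$left$keys),
                   c("stride_duration", "TOL", "GCTL"))
  expect_identical(colnames(kf$lib$right$keys),
                   c("stride_duration", "GCTR"))
  expect_true(all(kf$lib$left$curves >= 0))
})

test_that("stored curves keep their impulse through normalization", {
  kf <- knn_fixture()
  i <- 8
  bw_n <- kf$s$profile$body_weight * 9.81
  dur <- kf$s$strides$duration[i]
  grid_dt <- dur / (length(kf$lib$grid) - 1)
  imp <- sum((kf$lib$left$curves[i, -1] + kf$lib$left$curves[i, -101]) / 2) *
    grid_dt * bw_n
  expect_equal(imp, kf$targets$impulseL[i], tolerance = 0.02 * kf$targets$impulseL[i])
})

test_that("grid resampling round-trips a stride curve within 1% RMS", {
  kf <- knn_fixture()
  i <- 12
  sl <- kf$slices[[i]]
  dur <- kf$s$strides$duration[i]
  bw_n <- kf$s$profile$body_weight * 9.81
  back <- approx(kf$lib$grid * dur, kf$lib$left$curves[i, ] * bw_n,
                 xout = sl$t - sl$t[1], rule = 2)$y
  rel_rms <- sqrt(mean((back - sl$vgrf_left)^2)) / max(sl$vgrf_left)
  expect_lt(rel_rms, 0.01)
})

test_that("K = 1 with a library key returns that stride's curve exactly", {
  kf <- knn_fixture()
  q <- query_curves(kf$lib, kf$lib$left$keys[7, , drop = FALSE], "left", k = 1)
  expect_equal(as.numeric(q), kf$lib$left$curves[7, ])
  # averaging identical curves returns the same curve
  dup <- kf$lib
  dup$left$curves <- kf$lib$left$curves[rep(7, 8), ]
  dup$left$keys <- kf$lib$left$keys[rep(7, 8), ]
  q8 <- query_curves(dup, kf$lib$left$keys[7, , drop = FALSE], "left", k = 8)
  expect_equal(as.numeric(q8), kf$lib$left$curves[7, ])
})

test_that("kd-tree search equals exhaustive search", {
  kf <- knn_fixture()
  set.seed(14)
  for (foot in c("left", "right")) {
    d <- ncol(kf$lib[[foot]]$keys)
    keys <- matrix(runif(200 * d, 0.1, 1.4), ncol = d)
    for (k in c(1L, 5L, 8L)) {
      a <- attr(query_curves(kf$lib, keys, foot, k = k,
                             method = "exhaustive"), "neighbors")
      b <- attr(query_curves(kf$lib, keys, foot, k = k,
                             method = "kdtree"), "neighbors")
      expect_identical(b, a)
    }
  }
})

test_that("k beyond the library size clamps with a warning; empty library errors", {
  kf <- knn_fixture()
  expect_warning(
    q <- query_curves(kf$lib, kf$lib$left$keys[1, , drop = FALSE], "left",
                      k = nrow(kf$lib$left$curves) + 5L), "clamp")
  expect_length(as.numeric(q), 101L)
  empty <- kf$lib
  empty$left$curves <- empty$left$curves[0, , drop = FALSE]
  expect_error(query_curves(empty, kf$lib$left$keys[1, , drop = FALSE],
                            "left"), "empty")
  expect_error(query_curves(kf$lib, matrix(NA_real_, 1, 3), "left"), "finite")
})

test_that("a one-stride session assembles to the padded stride curve", {
  kf <- knn_fixture()
  st <- kf$s$strides[3, ]
  curve <- query_curves(kf$lib, kf$lib$left$keys[3, , drop = FALSE],
                        "left", k = 1)
  cont <- assemble_continuous(curve, st, body_weight = NULL,
                              n_samples = st$end_idx + 100)
  expect_true(all(cont[seq_len(st$start_idx)] == 0))
  expect_true(all(cont[(st$end_idx + 1):length(cont)] == 0))
  expect_gt(max(cont), 1)
  expect_error(
    assemble_continuous(curve[c(1, 1), ],
                        rbind(st, within(st, start_idx <- start_idx + 10)),
                        n_samples = 10000), "overlap")
})

test_that("oracle time parameters beat permuted ones on session NRMSE", {
  kf <- knn_fixture()
  s <- kf$s
  tt <- kf$targets
  bw <- s$profile$body_weight
  keys <- cbind(s$strides$duration, tt$TOL, tt$GCTL)
  gi <- round(s$truth$gait_interval * s$fs_sensor)
  rng <- (gi[1] + 1):gi[2]
  truth_n <- s$truth$force_left_bw[rng] * bw * 9.81
  session_nrmse <- function(k) {
    curves <- query_curves(kf$lib, k, "left", k = 8)
    nrmse(assemble_continuous(curves, s$strides, bw, s$fs_sensor,
                              nrow(s$sensor))[rng], truth_n)
  }
  e_oracle <- session_nrmse(keys)
  set.seed(2)
  e_perm <- session_nrmse(keys[sample(nrow(keys)), ])
  expect_lt(e_oracle, e_perm)
  expect_lt(e_oracle, 20)
})
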