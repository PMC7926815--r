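# Feature extraction and insole-derived target parameters.

flat_slice <- function(n = 100, speed = 1.5) {
  data.frame(speed = rep(speed, n), accel_forward = 0, accel_lateral = 0,
             accel_vertical = 9.81, gyro_x = 0, gyro_y = 0, gyro_z = 0,
             vertical_velocity = 0, vertical_displacement = 0.01,
             ground_track = 45)
}

test_that("the canonical feature table has exactly 27 named entries", {
  expect_length(feature_names(), 27L)
  expect_false(anyDuplicated(feature_names()) > 0)
  f <- extract_features(flat_slice(), 1.0)
  expect_identical(colnames(f), feature_names())
  expect_true(all(is.finite(as.numeric(f[1, ]))))
})

test_that("constant channels yield zero p-p and SD features", {
  f <- extract_features(flat_slice(), 1.0)
  pp_sd <- grep("_(pp|sd)$", colnames(f), value = TRUE)
  expect_true(all(f[, pp_sd] == 0))
  expect_equal(f$speed_mean, 1.5)
  expect_equal(f$stride_duration, 1.0)
  expect_equal(f$step_length, 0.75)       # mean speed x half stride
  expect_equal(f$cadence, 2.0)
})

test_that("linearly rising speed gives the textbook mean and range", {
  sl <- flat_slice(101)
  sl$speed <- seq(1, 2, length.out = 101)
  f <- extract_features(sl, 1.0)
  expect_equal(f$speed_mean, 1.5)
  expect_equal(f$speed_pp, 1.0)
  expect_equal(f$speed_max, 2.0)
  # both step-length quadratures agree for a linear profile
  f2 <- extract_features(sl, 1.0, step_length_method = "path")
  expect_equal(f2$step_length, f$step_length, tolerance = 1e-6)
})

test_that("short slices and missing channels are rejected", {
  expect_error(extract_features(flat_slice(5), 1.0), "degenerate")
  sl <- flat_slice()
  sl$speed <- NULL
  expect_error(extract_features(sl, 1.0), "speed")
})

test_that("stride duration feature matches the planned duration", {
  s <- mixed_session()
  ex <- extract_session(s$sensor, NULL, s$strides, s$profile$body_weight)
  expect_equal(ex$features$stride_duration, s$strides$duration,
               tolerance = 1 / 400 / min(s$strides$duration))
})

test_that("a rectangular force pulse yields the analytic targets", {
  t <- seq(0, 0.98, by = 0.02)
  f <- ifelse(t >= 0.1 & t < 0.7, 800, 0)
  sl <- data.frame(t = t, vgrf_left = f, vgrf_right = f)
  tg <- extract_targets(sl, body_weight = 72)
  expect_lt(abs(tg$TDL - 0.1), 0.021)      # within one insole sample
  expect_lt(abs(tg$TOL - 0.7), 0.021)
  expect_lt(abs(tg$GCTL - 0.6), 0.021)
  expect_equal(tg$peak_vgrfL, 800)
  expect_equal(tg$impulseL, 480, tolerance = 1e-6)
  expect_equal(tg$peak_vgrfL_bw, 800 / (72 * 9.81), tolerance = 1e-6)
})

test_that("an all-zero force flags zero contact without erroring", {
  t <- seq(0, 0.98, by = 0.02)
  sl <- data.frame(t = t, vgrf_left = 0, vgrf_right = ifelse(t < 0.5, 700, 0))
  expect_warning(tg <- extract_targets(sl, 72), "zero-contact")
  expect_equal(tg$peak_vgrfL, 0)
  expect_equal(tg$impulseL, 0)
  expect_equal(tg$GCTL, 0)
  expect_true(is.na(tg$TDL))
})

test_that("extracted targets match generator truth on clean strides", {
  s <- walk_session()
  slices <- session_slices(s)
  tt <- s$truth$targets
  for (i in c(10, 30, 50)) {
    tg <- suppressWarnings(extract_targets(slices[[i]],
                                           s$profile$body_weight))
    # single-edge event times land within one insole sample period of truth
    for (col in c("TDL", "TOL", "TDR", "TOR"))
      expect_lt(abs(tg[[col]] - tt[[col]][i]), 0.021,
                label = sprintf("%s stride %d error", col, i))
    # contact-measure targets accumulate the contact-threshold crossing
    # delay (~13 ms per edge at the 2% BW threshold): two edges for GCT,
    # four for double support
    expect_lt(abs(tg$GCTL - tt$GCTL[i]), 0.035)
    expect_lt(abs(tg$GCTR - tt$GCTR[i]), 0.035)
    expect_lt(abs(tg$double_support_time - tt$double_support_time[i]), 0.07)
    expect_lt(abs(tg$peak_vgrfL - tt$peak_vgrfL[i]),
              0.02 * tt$peak_vgrfL[i])
    expect_lt(abs(tg$impulseL - tt$impulseL[i]), 0.02 * tt$impulseL[i])
  }
})

test_that("body-weight normalization is linear and leaves times alone", {
  t <- seq(0, 0.98, by = 0.02)
  f <- ifelse(t >= 0.1 & t < 0.7, 800, 0)
  sl <- data.frame(t = t, vgrf_left = f, vgrf_right = f)
  a <- extract_targets(sl, 72, contact_threshold = 14)
  b <- extract_targets(sl, 144, contact_threshold = 14)
  expect_equal(b$peak_vgrfL_bw, a$peak_vgrfL_bw / 2)
  expect_equal(b$impulseL_bw, a$impulseL_bw / 2)
  expect_equal(b$TDL, a$TDL)
  expect_equal(b$GCTL, a$GCTL)
})

test_that("impulse is additive over a split stance", {
  # trapezoid consistency: impulses of the two window halves sum to the
  # whole-window impulse (the split point is a shared grid sample)
  t <- seq(0, 1, by = 0.02)
  f <- 50 + 700 * sin(pi * t)^2          # strictly positive: full contact
  sl <- function(tt, ff) data.frame(t = tt, vgrf_left = ff, vgrf_right = ff)
  imp <- function(tt, ff)
    extract_targets(sl(tt, ff), 72, contact_threshold = 1)$impulseL
  expect_equal(imp(t[t <= 0.5], f[t <= 0.5]) + imp(t[t >= 0.5], f[t >= 0.5]),
               imp(t, f), tolerance = 1e-9)
})

test_that("adding a constant heading leaves track range features unchanged", {
  s <- walk_session()
  sl <- s$sensor[(s$strides$start_idx[5] + 1):s$strides$end_idx[5], ]
  f1 <- extract_features(sl, 1.0)
  sl$ground_track <- sl$ground_track + 90
  f2 <- extract_features(sl, 1.0)
  expect_equal(f2$ground_track_pp, f1$ground_track_pp)
  expect_equal(f2$ground_track_sd, f1$ground_track_sd)
  expect_equal(f2$ground_track_abs_change, f1$ground_track_abs_change)
})
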