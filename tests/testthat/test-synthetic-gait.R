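# Force templates and the session simulator.

local_maxima <- function(f) which(diff(sign(diff(f))) == -2) + 1L

test_that("walking template has the M shape: two peaks, one valley, compact support", {
  f <- walking_vgrf_template(1.0, 0.6, 1.2, 1.2, 0.7, n_samples = 400)
  t <- attr(f, "t")
  mx <- local_maxima(f)
  expect_length(mx, 2L)
  expect_equal(max(f), 1.2, tolerance = 1e-6)
  expect_equal(sort(f[mx]), c(1.2, 1.2), tolerance = 1e-6)
  inner <- f[t > 0 & t < 0.6]
  mn <- local_maxima(-inner)
  expect_length(mn, 1L)
  expect_equal(inner[mn], 0.7, tolerance = 1e-6)
  expect_true(all(f[t >= 0.6] == 0))
  expect_equal(f[1L], 0)
  expect_lt(max(abs(diff(f))), 0.05)  # continuity at the sampling scale

  # distinct peaks survive as the two maxima
  f2 <- walking_vgrf_template(1.1, 0.65, 1.4, 1.1, 0.6, n_samples = 440)
  expect_equal(sort(f2[local_maxima(f2)]), c(1.1, 1.4), tolerance = 1e-6)
})

test_that("running template has a single interior peak and zero flight force", {
  f <- running_vgrf_template(0.8, 0.3, 2.5, n_samples = 320)
  t <- attr(f, "t")
  expect_length(local_maxima(f), 1L)
  expect_equal(max(f), 2.5, tolerance = 1e-4)
  expect_true(all(f[t >= 0.3] == 0))
  expect_gt(mean(f == 0), 0.5)  # flight-dominated stride at this duty
})

test_that("template preconditions are enforced", {
  expect_error(walking_vgrf_template(1, 1.0, 1.2, 1.2, 0.7), "invalid duty")
  expect_error(walking_vgrf_template(1, 1.2, 1.2, 1.2, 0.7), "invalid duty")
  expect_error(walking_vgrf_template(1, 0.6, -1, 1.2, 0.7), "positive")
  expect_error(walking_vgrf_template(1, 0.6, 1.2, 1.2, 1.3), "valley")
  expect_error(running_vgrf_template(0.8, 0.9, 2.5), "invalid duty")
  expect_error(running_vgrf_template(0.8, 0.3, -2), "positive")
  expect_error(walking_vgrf_template(1, 0.6, 1.2, 1.2, 0.7, n_samples = 10),
               "n_samples")
})

test_that("auto-scaling fixes the stride-averaged force", {
  # oracle: the stride-average of the returned samples approximates the
  # time-average integral; both templates must hit the target within 1%
  for (tm in c(1.0, 0.5)) {
    fw <- walking_vgrf_template(1.0, 0.62, 1.2, 1.2, 0.7, n_samples = 2000,
                                scale_to_impulse = TRUE, target_mean = tm)
    fr <- running_vgrf_template(0.8, 0.35, 2.5, n_samples = 2000,
                                scale_to_impulse = TRUE, target_mean = tm)
    expect_equal(mean(fw), tm, tolerance = 0.01)
    expect_equal(mean(fr), tm, tolerance = 0.01)
  }
})

test_that("subject profile invariants are validated", {
  expect_error(subject_profile(walk_duty_factor = 0.45), "walk_duty_factor")
  expect_error(subject_profile(run_duty_factor = 0.55), "run_duty_factor")
  expect_error(subject_profile(walk_peak_range = c(1.0, 2.5)), "strictly below")
  expect_error(subject_profile(insole_swing_artifact_scale = -0.1),
               "non-negative")
})

test_that("gait plan validates speeds and draws durations against speed", {
  expect_error(gait_plan("walk", 0.5, seed = 1), "supported interval")
  expect_error(gait_plan("walk", 6.2, seed = 1), "supported interval")
  plan <- gait_plan_walk_run(300, seed = 3)
  expect_lt(cor(plan$speed, plan$stride_duration), -0.5)
})

test_that("simulated walk strides have in-range double peaks and matching labels", {
  s <- walk_session()
  tt <- s$truth$targets
  expect_true(all(tt$peak_vgrfL_bw >= 1.0 & tt$peak_vgrfL_bw <= 1.5))
  expect_true(all(tt$peak_vgrfR_bw[-1L] >= 1.0 & tt$peak_vgrfR_bw[-1L] <= 1.5))
  # observed insole curves keep two peaks in range (no noise, no artifact)
  slices <- session_slices(s)
  for (i in c(5, 20, 40)) {
    f <- slices[[i]]$vgrf_left / (s$profile$body_weight * 9.81)
    pk <- f[local_maxima(f)]
    pk <- pk[pk > 0.5]          # the stance peaks, not numerical ripples
    expect_length(pk, 2L)
    expect_true(all(pk >= 1.0 & pk <= 1.5))
  }
  # contact labels equal force > 0 everywhere at zero artifact scale
  expect_identical(s$truth$contact_left, s$truth$force_left_bw > 0)
  expect_identical(s$truth$contact_right, s$truth$force_right_bw > 0)
})

test_that("a 60 s plan at 1.0 s strides yields 60 strides", {
  s <- walk_session()
  expect_identical(nrow(s$strides), 60L)
  expect_equal(s$strides$duration, rep(1.0, 60))
})

test_that("mode dichotomy: walking has double support, running has flight", {
  tt <- mixed_session()$truth$targets
  walk <- tt[tt$mode == "walk", ]
  run <- tt[tt$mode == "run", ]
  expect_true(all(walk$double_support_time > 0))
  expect_true(all(walk$flight_time == 0))
  expect_true(all(run$flight_time > 0))
  expect_true(all(run$double_support_time == 0))
})

test_that("identical profile, plan and seed reproduce the session bitwise", {
  prof <- clean_profile()
  plan <- gait_plan_walk_run(10, seed = 8, profile = prof)
  a <- simulate_session(prof, plan, seed = 9)
  b <- simulate_session(prof, plan, seed = 9)
  expect_identical(a$sensor, b$sensor)
  expect_identical(a$insole, b$insole)
  expect_identical(a$truth$targets, b$truth$targets)
})

test_that("speed correlates negatively with GCT and positively with peak vGRF", {
  prof <- clean_profile()
  plan <- gait_plan_walk_run(500, walk_frac = 0.7, seed = 33, profile = prof)
  s <- simulate_session(prof, plan, fs_sensor = 100, fs_insole = 50, seed = 34)
  tt <- s$truth$targets
  expect_lt(cor(tt$speed, tt$GCTL), 0)
  expect_gt(cor(tt$speed, tt$peak_vgrfL_bw), 0)
})

test_that("incompatible sampling rates are a resampling-config error", {
  prof <- clean_profile()
  plan <- gait_plan("walk", 1.5, 1.0, seed = 2)
  expect_error(simulate_session(prof, plan, fs_sensor = 400, fs_insole = 60),
               "integer multiple")
})

test_that("insole artifacts: quantization only at scale 0, second-half swing bumps otherwise", {
  contact <- c(rep(1, 60), rep(0, 60), rep(1, 40), rep(0, 40))
  true_f <- ifelse(contact == 1, 700, 0)
  q <- apply_insole_artifacts(true_f, contact, 72, artifact_scale = 0)
  expect_equal(q, round(true_f / 5) * 5)
  obs <- apply_insole_artifacts(true_f, contact, 72, artifact_scale = 0.1,
                                seed = 4)
  expect_true(all(obs >= 0))
  swing1 <- 61:120
  first_half <- swing1[seq_len(30)]
  second_half <- swing1[31:60]
  expect_true(all(obs[first_half] == 0))
  expect_gt(mean(obs[second_half]), 0)
  expect_true(all(obs[second_half] <= 0.1 * 72 * 9.81 + 5))
  expect_error(apply_insole_artifacts(true_f, contact, 72,
                                      artifact_scale = -1), "non-negative")
  expect_error(apply_insole_artifacts(true_f, contact[-1], 72), "aligned")
})

test_that("sensor kinematics are consistent: displacement double-integrates acceleration", {
  s <- walk_session()
  dt <- 1 / s$fs_sensor
  vz <- cumsum(c(0, (s$sensor$accel_vertical[-1] - 9.81) * dt))
  z <- cumsum(c(0, vz[-1] * dt))
  expect_lt(max(abs(z - s$sensor$vertical_displacement)), 1e-6)
})
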