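# Shared synthetic fixtures, generated once per test run and memoised.
# Clean sessions (zero sensor noise, zero insole artifact) are the reference
# for exactness checks; noisy sessions exercise robustness.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, make) {
  if (!exists(key, .fixture_cache)) assign(key, make(), .fixture_cache)
  get(key, .fixture_cache)
}

clean_profile <- function(...) {
  subject_profile(sensor_noise_sd = 0, insole_swing_artifact_scale = 0, ...)
}

# 60 s of zero-noise walking at 1.0 s strides, 400/50 Hz
walk_session <- function() fixture("walk", function() {
  prof <- clean_profile()
  plan <- gait_plan("walk"[rep(1, 60)], speed = rep(1.5, 60),
                    stride_duration = rep(1.0, 60), seed = 11)
  simulate_session(prof, plan, seed = 12)
})

# mixed walk-run session, zero noise
mixed_session <- function() fixture("mixed", function() {
  prof <- clean_profile()
  plan <- gait_plan_walk_run(60, seed = 42, profile = prof)
  simulate_session(prof, plan, seed = 43)
})

# pure running session, zero noise
run_session <- function() fixture("run", function() {
  prof <- clean_profile()
  plan <- gait_plan_walk_run(40, walk_frac = 0, seed = 19, profile = prof)
  simulate_session(prof, plan, seed = 20)
})

# session with synchronization jumps
jump_session <- function() fixture("jumps", function() {
  prof <- clean_profile()
  plan <- gait_plan_walk_run(20, seed = 5, profile = prof)
  simulate_session(prof, plan, jumps = TRUE, seed = 6)
})

# per-stride insole slices + truth-aligned extraction of a session
session_slices <- function(s) {
  lapply(seq_len(nrow(s$strides)), function(i)
    slice_insole(s$insole, s$strides[i, ], 0, s$fs_sensor))
}

# shift an insole trace's clock by d seconds
shift_insole <- function(insole, d) {
  out <- insole
  out$t <- out$t + d
  attr(out, "fs") <- attr(insole, "fs")
  class(out) <- class(insole)
  out
}

# feature table with planted structure: 6 informative features drive the
# targets, 3 redundant near-copies (|r| > 0.9 with an informative one) and
# 3 pure-noise features (|r| <= 0.3 to every target)
planted_tables <- function(n = 400, seed = 1) {
  set.seed(seed)
  inf <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, paste0("inf", 1:6)))
  red <- inf[, 1:3] + matrix(rnorm(n * 3, 0, 0.05), n, 3)
  colnames(red) <- paste0("red", 1:3)
  noise <- matrix(rnorm(n * 3), n, 3,
                  dimnames = list(NULL, paste0("noise", 1:3)))
  targets <- data.frame(
    y1 = inf[, 1] + 0.5 * inf[, 2] + rnorm(n, 0, 0.1),
    y2 = inf[, 3] - inf[, 4] + rnorm(n, 0, 0.1),
    y3 = inf[, 5] + rnorm(n, 0, 0.1),
    y4 = inf[, 6] + rnorm(n, 0, 0.1))
  list(features = data.frame(inf, red, noise), targets = targets)
}

# feature/target tables of a fast 100 Hz session for model tests
model_tables <- function(n_strides, seed, profile = clean_profile()) {
  plan <- gait_plan_walk_run(n_strides, seed = seed, profile = profile)
  s <- simulate_session(profile, plan, fs_sensor = 100, fs_insole = 50,
                        seed = seed + 1)
  ex <- extract_session(s$sensor, s$insole, s$strides, profile$body_weight)
  list(session = s, features = ex$features, targets = ex$targets)
}
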