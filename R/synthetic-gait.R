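# Synthetic walk-run gait generator: paired torso INS/GPS and insole force
# streams with full per-stride and per-sample ground truth.
#
# Force templates are compactly supported smooth bumps over the stance phase:
# walking uses a double-peak "M" profile (heel-strike peak, mid-stance valley,
# push-off peak), running a single-peak inverted-"V" profile. Amplitudes are in
# multiples of body weight (xBW). The generator solves the stance duration from
# the drawn peak so that the stride-averaged total vertical force of a steady
# stride equals 1 BW (the body is supported on average), which automatically
# yields duty factors > 0.5 in walking (double support) and < 0.5 in running
# (flight phases).

# Mean/peak ratio of the running bump shape sin(pi*u)^1.5 over stance,
# integral_0^1 sin(pi*u)^1.5 du. A plain raised cosine (ratio 0.5) would make a
# 2.0 xBW running peak degenerate (duty factor exactly 0.5, zero flight time);
# the sharpened bump keeps duty < 0.5 over the whole 2.0-2.9 xBW range.
RUN_SHAPE_MEAN <- 0.5562810

#' Subject profile for the synthetic gait generator
#'
#' Bundles the anthropometric and signal-quality parameters of a simulated
#' subject. Peak vertical ground reaction forces are drawn per stride from
#' `walk_peak_range` (double-peak "M" strides) or `run_peak_range`
#' (single-peak strides), in multiples of body weight; walking peaks stay
#' strictly below running peaks. Duty factors (fraction of the stride a foot
#' is in stance) are nominal values used only when impulse balancing is
#' disabled; with balancing (the default) the stance time follows from the
#' drawn peak.
#'
#' @param body_weight body mass in kg, > 0
#' @param height stature in cm, > 0
#' @param walk_peak_range,run_peak_range numeric length-2 intervals of peak
#'   vGRF in xBW; defaults 1.0-1.5 (walk) and 2.0-2.9 (run)
#' @param walk_duty_factor nominal walking duty factor, must exceed 0.5
#' @param run_duty_factor nominal running duty factor, must be below 0.5
#' @param sensor_noise_sd dimensionless scale of additive white sensor noise
#'   (multiplies per-channel base noise amplitudes); 0 disables noise
#' @param insole_swing_artifact_scale magnitude bound, in xBW, of the spurious
#'   insole force injected during the second half of swing phases
#' @param valley_ratio mid-stance valley of the walking "M" curve as a
#'   fraction of the peak
#' @param peak_jitter_sd stride-to-stride SD of the drawn peak, xBW
#' @param stride_t0,stride_slope,stride_slope_run intercept (s) and slopes
#'   (s per m/s) of the piecewise-linear speed to stride-duration relation
#'   used when a plan draws durations automatically: duration decreases with
#'   speed, steeply over walking speeds and only mildly beyond (running
#'   cadence rises slowly with speed)
#' @param insole_area_cm2 effective sensor area mapping the insole pressure
#'   resolution (N/cm2) to a force quantization step
#' @return an object of class `subject_profile`
#' @export
subject_profile <- function(body_weight = 72, height = 178,
                            walk_peak_range = c(1.0, 1.5),
                            run_peak_range = c(2.0, 2.9),
                            walk_duty_factor = 0.62,
                            run_duty_factor = 0.40,
                            sensor_noise_sd = 0.05,
                            insole_swing_artifact_scale = 0.10,
                            valley_ratio = 0.55,
                            peak_jitter_sd = 0.03,
                            stride_t0 = 1.232,
                            stride_slope = 0.12,
                            stride_slope_run = 0.03,
                            insole_area_cm2 = 5) {
  stopifnot(body_weight > 0, height > 0,
            length(walk_peak_range) == 2L, length(run_peak_range) == 2L,
            walk_peak_range[1] <= walk_peak_range[2],
            run_peak_range[1] <= run_peak_range[2],
            sensor_noise_sd >= 0, valley_ratio > 0, valley_ratio < 1)
  if (walk_duty_factor <= 0.5)
    stopf("walk_duty_factor must exceed 0.5 (double support in walking)")
  if (run_duty_factor >= 0.5)
    stopf("run_duty_factor must be below 0.5 (flight phases in running)")
  if (max(walk_peak_range) >= min(run_peak_range))
    stopf("walking peak range must lie strictly below the running peak range")
  if (insole_swing_artifact_scale < 0)
    stopf("insole_swing_artifact_scale must be non-negative")
  structure(list(
    body_weight = body_weight, height = height,
    walk_peak_range = walk_peak_range, run_peak_range = run_peak_range,
    walk_duty_factor = walk_duty_factor, run_duty_factor = run_duty_factor,
    sensor_noise_sd = sensor_noise_sd,
    insole_swing_artifact_scale = insole_swing_artifact_scale,
    valley_ratio = valley_ratio, peak_jitter_sd = peak_jitter_sd,
    stride_t0 = stride_t0, stride_slope = stride_slope,
    stride_slope_run = stride_slope_run,
    insole_area_cm2 = insole_area_cm2
  ), class = "subject_profile")
}

#' Gait plan: the stride-by-stride schedule of a session
#'
#' @param mode character vector, each element "walk" or "run"
#' @param speed per-stride forward speed, m/s, within 0.77-5.90 (the
#'   generator's supported interval)
#' @param stride_duration per-stride duration in s, or NULL to draw from the
#'   profile's speed-duration relation (negatively associated with speed)
#' @param seed integer RNG seed stored with the plan (mandatory)
#' @param profile subject profile used when durations are drawn
#' @return data.frame of class `gait_plan` with columns mode, speed,
#'   stride_duration
#' @export
gait_plan <- function(mode, speed, stride_duration = NULL, seed,
                      profile = subject_profile()) {
  stopifnot(length(mode) == length(speed), length(mode) >= 1L)
  if (missing(seed)) stopf("gait_plan requires an explicit seed")
  mode <- match.arg(mode, c("walk", "run"), several.ok = TRUE)
  if (any(speed < 0.77 | speed > 5.90))
    stopf("speed outside the supported interval [0.77, 5.90] m/s")
  if (is.null(stride_duration)) {
    set.seed(seed)
    # stride-to-stride timing variability (a few percent of the duration)
    # keeps duration informative beyond what speed already carries; the
    # speed dependence flattens above walking speeds
    knee <- 2.2
    stride_duration <- profile$stride_t0 -
      profile$stride_slope * pmin(speed, knee) -
      profile$stride_slope_run * pmax(speed - knee, 0) +
      stats::rnorm(length(speed), 0, 0.045)
    stride_duration <- pmin(pmax(stride_duration, 0.55), 1.45)
  }
  if (any(stride_duration <= 0)) stopf("stride_duration must be positive")
  structure(
    data.frame(mode = mode, speed = speed, stride_duration = stride_duration,
               stringsAsFactors = FALSE),
    seed = as.integer(seed), class = c("gait_plan", "data.frame"))
}

#' Default walk-run plan mirroring a mixed outdoor session
#'
#' Walking strides (a `walk_frac` fraction of the session, leading block) are
#' followed by running strides. Speeds evolve as a reflected random walk
#' inside each mode's speed band so consecutive strides differ smoothly;
#' stride durations follow the profile's speed-duration relation.
#'
#' @param n_strides total stride count
#' @param walk_frac fraction of strides that are walking (default 0.894, the
#'   composition of a walking-dominated training session)
#' @param speed_walk,speed_run speed bands (m/s) per mode
#' @param seed integer seed
#' @param profile subject profile
#' @export
gait_plan_walk_run <- function(n_strides, walk_frac = 0.894,
                               speed_walk = c(0.77, 2.2),
                               speed_run = c(2.2, 5.9),
                               seed, profile = subject_profile()) {
  stopifnot(n_strides >= 1L, walk_frac >= 0, walk_frac <= 1)
  if (missing(seed)) stopf("gait_plan_walk_run requires an explicit seed")
  set.seed(seed)
  n_walk <- round(n_strides * walk_frac)
  n_run <- n_strides - n_walk
  rw <- function(n, lo, hi, step) {
    if (n == 0L) return(numeric(0))
    v <- numeric(n)
    v[1] <- stats::runif(1, lo, hi)
    if (n > 1L) for (i in 2:n) {
      x <- v[i - 1L] + stats::rnorm(1, 0, step)
      # reflect at the band edges
      if (x < lo) x <- lo + (lo - x)
      if (x > hi) x <- hi - (x - hi)
      v[i] <- min(max(x, lo), hi)
    }
    v
  }
  speeds <- c(rw(n_walk, speed_walk[1], speed_walk[2], 0.15),
              rw(n_run, speed_run[1], speed_run[2], 0.25))
  modes <- c(rep("walk", n_walk), rep("run", n_run))
  gait_plan(modes, speeds, stride_duration = NULL,
            seed = seed + 1L, profile = profile)
}

# ---- Force templates ---------------------------------------------------------

# Continuous stance shapes evaluated at u in [0, 1] (normalized stance time).
walk_shape <- function(u, peak1, peak2, valley) {
  # half-cosine segments through knots 0 -> peak1 -> valley -> peak2 -> 0 at
  # quarter points of stance: two local maxima, one interior minimum, C1
  knots <- c(0, peak1, valley, peak2, 0)
  seg <- pmin(pmax(floor(u * 4), 0), 3)
  s <- u * 4 - seg
  a <- knots[seg + 1L]
  b <- knots[seg + 2L]
  out <- a + (b - a) * (0.5 - 0.5 * cos(pi * s))
  out[u < 0 | u > 1] <- 0
  out
}

run_shape <- function(u, peak) {
  out <- peak * sin(pi * pmin(pmax(u, 0), 1))^1.5
  out[u < 0 | u > 1] <- 0
  out
}

template_checks <- function(stride_duration, gct, n_samples) {
  if (!(stride_duration > 0)) stopf("stride_duration must be positive")
  if (gct <= 0) stopf("gct must be positive")
  if (gct >= stride_duration)
    stopf("invalid duty: gct (%.3f s) must be shorter than the stride (%.3f s)",
          gct, stride_duration)
  if (n_samples < 20L) stopf("n_samples must be at least 20")
}

#' Walking ("M") vertical ground reaction force template
#'
#' One foot's vGRF over one stride, in multiples of body weight: zero outside
#' the stance interval `[0, gct]`, with exactly two local maxima (`peak1` at
#' heel strike, `peak2` at push-off), one interior local minimum (`valley` at
#' mid-stance), and continuous everywhere. Samples are taken on the uniform
#' grid `t = (0:(n_samples-1)) / n_samples * stride_duration`.
#'
#' With `scale_to_impulse = TRUE` the curve is rescaled so its stride-average
#' equals `target_mean` xBW (default 1, a one-legged support balance; use 0.5
#' for one of two alternating feet).
#'
#' @param stride_duration stride duration, s
#' @param gct ground contact (stance) time, s, `0 < gct < stride_duration`
#' @param peak1,peak2 the two stance peaks, xBW, > 0
#' @param valley mid-stance valley, xBW, `< min(peak1, peak2)`
#' @param n_samples number of samples (>= 20)
#' @param scale_to_impulse rescale amplitude to a fixed stride-average force
#' @param target_mean stride-average force target, xBW, when rescaling
#' @return numeric vector of length `n_samples`, xBW; attribute `t` holds the
#'   sample times
#' @export
walking_vgrf_template <- function(stride_duration, gct, peak1, peak2, valley,
                                  n_samples = 400L, scale_to_impulse = FALSE,
                                  target_mean = 1.0) {
  template_checks(stride_duration, gct, n_samples)
  if (peak1 <= 0 || peak2 <= 0) stopf("peaks must be positive")
  if (valley >= min(peak1, peak2))
    stopf("valley must lie below both peaks")
  if (valley < 0) stopf("valley must be non-negative")
  t <- (seq_len(n_samples) - 1L) / n_samples * stride_duration
  f <- walk_shape(t / gct, peak1, peak2, valley)
  if (scale_to_impulse) f <- f * target_mean / mean(f)
  attr(f, "t") <- t
  f
}

#' Running (inverted-"V") vertical ground reaction force template
#'
#' Single-peak stance bump `peak * sin(pi*u)^1.5` over `[0, gct]`, zero in the
#' flight part of the stride. Same sampling and scaling conventions as
#' [walking_vgrf_template()].
#'
#' @inheritParams walking_vgrf_template
#' @param peak stance peak, xBW, > 0
#' @export
running_vgrf_template <- function(stride_duration, gct, peak,
                                  n_samples = 400L, scale_to_impulse = FALSE,
                                  target_mean = 1.0) {
  template_checks(stride_duration, gct, n_samples)
  if (peak <= 0) stopf("peak must be positive")
  t <- (seq_len(n_samples) - 1L) / n_samples * stride_duration
  f <- run_shape(t / gct, peak)
  if (scale_to_impulse) f <- f * target_mean / mean(f)
  attr(f, "t") <- t
  f
}

# Stance time satisfying the per-foot impulse balance: stride-mean of one
# foot's force = 0.5 xBW. Walking M mean over stance is (p1+p2+v)/4 exactly
# (each half-cosine segment averages its endpoint mean); running mean is
# peak * RUN_SHAPE_MEAN.
balanced_gct <- function(mode, stride_duration, peak, valley_ratio) {
  if (mode == "walk") {
    m <- (2 + valley_ratio) * peak / 4
  } else {
    m <- peak * RUN_SHAPE_MEAN
  }
  0.5 * stride_duration / m
}

# ---- Insole artifacts --------------------------------------------------------

#' Insole measurement model: quantization and swing-phase artifacts
#'
#' Converts a true per-foot force curve into what a pressure insole would
#' report: forces are quantized to the step implied by the pressure
#' resolution and effective sensor area, and during the *second half* of each
#' swing interval (foot airborne, moving back toward the ground) a spurious
#' positive force of magnitude at most `artifact_scale` xBW is injected. The
#' first half of each swing stays zero (the foot moves up, away from the
#' insole).
#'
#' @param true_force true force samples, N
#' @param contact_labels binary/logical vector, same length: 1 where the foot
#'   truly contacts the ground
#' @param body_weight subject mass, kg (scales the artifact)
#' @param resolution pressure resolution, N/cm2 (default 1.0)
#' @param artifact_scale artifact magnitude bound, xBW, >= 0
#' @param area_cm2 effective sensor area mapping resolution to a force step
#' @param seed optional integer seed for the artifact draw
#' @return observed force, N, same length; non-negative
#' @export
apply_insole_artifacts <- function(true_force, contact_labels, body_weight,
                                   resolution = 1.0, artifact_scale = 0.10,
                                   area_cm2 = 5, seed = NULL) {
  if (length(true_force) != length(contact_labels))
    stopf("force and contact label vectors must be aligned (same length)")
  if (artifact_scale < 0) stopf("artifact_scale must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  step <- resolution * area_cm2
  bw_n <- body_weight * GRAVITY
  out <- true_force
  if (artifact_scale > 0) {
    swings <- true_runs(!(contact_labels > 0))
    if (nrow(swings)) for (k in seq_len(nrow(swings))) {
      s <- swings$start[k]; e <- swings$end[k]
      len <- e - s + 1L
      if (len < 2L) next
      h_start <- s + ceiling(len / 2)        # second half of the swing
      if (h_start > e) next
      m <- e - h_start + 1L
      amp <- stats::runif(1, 0.3, 1.0) * artifact_scale * bw_n
      bump <- amp * sin(pi * seq_len(m) / (m + 1L))
      out[h_start:e] <- out[h_start:e] + bump
    }
  }
  pmax(round(out / step) * step, 0)
}

# ---- Session synthesis -------------------------------------------------------

#' Simulate a paired sensor + insole gait session
#'
#' Generates a kinematically consistent 400 Hz torso INS/GPS trace and a
#' 50 Hz per-foot insole force trace for the given plan, together with the
#' stride table and full ground truth. The vertical displacement channel is
#' (discretely) the double integral of vertical acceleration minus gravity;
#' the left and right feet are phase-shifted by half a stride; the insole
#' trace is the true force sampled at `fs_insole`, quantized, and corrupted
#' by the swing artifact of the profile.
#'
#' Optionally the session is book-ended by standing phases containing
#' synchronization jumps (sharp co-occurring spikes in total force and
#' vertical velocity).
#'
#' @param profile a [subject_profile()]
#' @param plan a [gait_plan()] (or [gait_plan_walk_run()]) schedule
#' @param fs_sensor sensor sampling rate, Hz (must be an integer multiple of
#'   `fs_insole`)
#' @param fs_insole insole sampling rate, Hz
#' @param jumps add synchronization jumps in standing phases at both ends
#' @param lead_in standing time before the first stride, s
#' @param seed integer seed; defaults to the plan's seed
#' @return list of class `gait_session` with elements `sensor` (data.frame,
#'   `sensor_trace`), `insole` (`insole_trace`), `strides` (`stride_table`),
#'   and `truth` (per-stride targets, per-sample true forces in xBW and
#'   contact labels at both rates, jump times)
#' @export
simulate_session <- function(profile, plan, fs_sensor = 400, fs_insole = 50,
                             jumps = FALSE, lead_in = 1.0, seed = NULL) {
  stopifnot(inherits(profile, "subject_profile"), nrow(plan) >= 1L)
  if (fs_sensor %% fs_insole != 0)
    stopf("resampling config error: fs_sensor (%g) must be an integer multiple of fs_insole (%g)",
          fs_sensor, fs_insole)
  seed <- seed %||% attr(plan, "seed")
  if (is.null(seed)) stopf("a seed is required (plan carries none)")
  set.seed(seed)

  n_str <- nrow(plan)
  jump_gap <- 2.5                     # standing segment length around a jump
  pre <- if (jumps) jump_gap else lead_in
  post <- if (jumps) jump_gap else 1.0
  t_start <- pre + c(0, cumsum(plan$stride_duration))[seq_len(n_str)]
  total <- pre + sum(plan$stride_duration) + post
  n <- round(total * fs_sensor)
  t <- (seq_len(n) - 1L) / fs_sensor
  dt <- 1 / fs_sensor

  # per-stride drawn parameters ------------------------------------------------
  peak <- numeric(n_str); gct <- numeric(n_str); amp_z <- numeric(n_str)
  for (i in seq_len(n_str)) {
    mode <- plan$mode[i]; v <- plan$speed[i]
    rng <- if (mode == "walk") profile$walk_peak_range else profile$run_peak_range
    band <- if (mode == "walk") c(0.77, 2.2) else c(2.2, 5.9)
    frac <- min(max((v - band[1]) / (band[2] - band[1]), 0), 1)
    p <- rng[1] + frac * (rng[2] - rng[1]) + stats::rnorm(1, 0, profile$peak_jitter_sd)
    peak[i] <- min(max(p, rng[1]), rng[2])
    gct[i] <- balanced_gct(mode, plan$stride_duration[i], peak[i],
                           profile$valley_ratio)
    base_amp <- if (mode == "walk") 0.020 + 0.002 * v else 0.050 + 0.003 * v
    amp_z[i] <- base_amp * (1 + stats::rnorm(1, 0, 0.10))
  }
  # per-stride multiplicative jitter of the oscillation amplitudes
  # (log-normal, median 1, roughly 30% CV as observed for torso
  # accelerations stride to stride) and random second-harmonic content:
  # stride style varies around the speed-driven trend, so amplitude features
  # carry information without being collinear with speed, and range/SD
  # statistics of one channel do not collapse onto each other
  jit <- matrix(exp(stats::rnorm(7L * n_str, 0, 0.28)), n_str, 7L)
  harm <- matrix(stats::runif(7L * n_str, 0, 0.6), n_str, 7L)

  # continuous per-foot true force (xBW) at the sensor rate --------------------
  force_l <- numeric(n); force_r <- numeric(n)
  place_stance <- function(force, t0, gct_i, mode, p, truncate_at = Inf) {
    tend <- min(t0 + gct_i, truncate_at)
    i0 <- max(1L, floor(t0 * fs_sensor) + 1L)
    i1 <- min(n, ceiling(tend * fs_sensor) + 1L)
    if (i1 < i0) return(force)
    u <- (t[i0:i1] - t0) / gct_i
    shp <- if (mode == "walk") {
      walk_shape(u, p, p, profile$valley_ratio * p)
    } else run_shape(u, p)
    shp[t[i0:i1] >= truncate_at] <- 0
    force[i0:i1] <- force[i0:i1] + shp
    force
  }
  gait_end <- pre + sum(plan$stride_duration)
  for (i in seq_len(n_str)) {
    T_i <- plan$stride_duration[i]
    # the right stance of a walking stride carries over the boundary; truncate
    # it at a walk->run transition (push-off into flight) and at the gait end
    trunc_r <- Inf
    if (plan$mode[i] == "walk") {
      nxt_end <- t_start[i] + T_i
      if (i == n_str || plan$mode[min(i + 1L, n_str)] == "run")
        trunc_r <- nxt_end
    }
    trunc_r <- min(trunc_r, gait_end)
    force_l <- place_stance(force_l, t_start[i], gct[i], plan$mode[i], peak[i],
                            truncate_at = gait_end)
    force_r <- place_stance(force_r, t_start[i] + T_i / 2, gct[i],
                            plan$mode[i], peak[i], truncate_at = trunc_r)
  }
  # standing phases: weight split evenly between the feet (the boundary
  # sample at the first touch-down is still standing, so the force never
  # shows a spurious one-sample flight gap there)
  standing <- t <= pre | t >= gait_end
  force_l[standing] <- 0.5
  force_r[standing] <- 0.5

  # synchronization jumps -------------------------------------------------------
  jump_times <- numeric(0)
  z_jump <- numeric(n)
  if (jumps) {
    D <- 0.44; H <- 0.25
    add_jump <- function(t0) {
      in_j <- t >= t0 & t <= t0 + D
      z_jump[in_j] <<- z_jump[in_j] + H * sin(pi * (t[in_j] - t0) / D)^2
      tp <- t0 + D / 4                      # vertical-velocity peak time
      # takeoff force spike (detected), flight, softer landing spike
      spike <- function(center, width, amp) {
        in_s <- t >= center - width / 2 & t <= center + width / 2
        amp / 2 * (0.5 + 0.5 * cos(pi * (t[in_s] - center) / (width / 2)))
      }
      in_s <- t >= tp - 0.1 & t <= tp + 0.1
      sp <- spike(tp, 0.2, 3.5)
      force_l[in_s] <<- sp; force_r[in_s] <<- sp
      in_f <- t > tp + 0.1 & t < t0 + 3 * D / 4
      force_l[in_f] <<- 0; force_r[in_f] <<- 0
      in_l <- t >= t0 + 3 * D / 4 & t <= t0 + 3 * D / 4 + 0.2
      sp2 <- spike(t0 + 3 * D / 4 + 0.1, 0.2, 2.0)
      force_l[in_l] <<- sp2; force_r[in_l] <<- sp2
      jump_times <<- c(jump_times, tp)
    }
    add_jump(pre - jump_gap + 1.0)
    add_jump(gait_end + 1.0)
  }

  # torso kinematics ------------------------------------------------------------
  z <- numeric(n); speed <- numeric(n); acc_fwd <- numeric(n)
  acc_lat <- numeric(n); gx <- numeric(n); gy <- numeric(n); gz <- numeric(n)
  track <- 45 + 3 * sin(2 * pi * t / 60)
  for (i in seq_len(n_str)) {
    T_i <- plan$stride_duration[i]; v <- plan$speed[i]
    i0 <- floor(t_start[i] * fs_sensor) + 1L
    i1 <- min(n, ceiling((t_start[i] + T_i) * fs_sensor))
    tau <- t[i0:i1] - t_start[i]
    ph2 <- 4 * pi * tau / T_i            # step-period phase (2 bounces/stride)
    ph1 <- 2 * pi * tau / T_i            # stride-period phase (L/R sway)
    z[i0:i1] <- amp_z[i] * (1 - cos(ph2))
    speed[i0:i1] <- v * (1 + 0.06 * jit[i, 1L] *
                           (sin(ph2 + 1.0) + harm[i, 1L] * sin(2 * ph2 + 0.4)))
    acc_fwd[i0:i1] <- 0.35 * v * jit[i, 2L] *
      (sin(ph2 + 0.7) + harm[i, 2L] * sin(2 * ph2 + 1.1))
    # the sway fundamental dominates so its sign still separates the feet
    acc_lat[i0:i1] <- (0.5 + 0.1 * v) * jit[i, 3L] *
      (cos(ph1) + 0.3 * harm[i, 3L] * cos(2 * ph1 + 0.2))
    gx[i0:i1] <- 0.15 * jit[i, 4L] * (cos(ph1) + harm[i, 4L] * cos(2 * ph1 + 0.8))
    gy[i0:i1] <- 0.10 * jit[i, 5L] * (sin(ph2 + 0.3) + harm[i, 5L] * sin(2 * ph2 + 1.3))
    gz[i0:i1] <- 0.12 * jit[i, 6L] * (sin(ph1 + 1.2) + harm[i, 6L] * sin(2 * ph1 + 0.5))
    track[i0:i1] <- track[i0:i1] + (0.8 + 0.5 * v) * jit[i, 7L] *
      (sin(ph1 + 0.5) + harm[i, 7L] * sin(2 * ph1 + 1.0))
  }
  z <- z + z_jump
  # vertical velocity / acceleration by discrete differentiation so that
  # displacement is exactly the double integral of (accel_vertical - g)
  vz <- c(0, diff(z)) / dt
  az <- c(0, diff(vz)) / dt + GRAVITY

  nz <- profile$sensor_noise_sd
  noise <- function(scale) if (nz > 0) stats::rnorm(n, 0, nz * scale) else 0
  sensor <- data.frame(
    t = t,
    accel_forward = acc_fwd + noise(1.0),
    accel_lateral = acc_lat + noise(1.0),
    accel_vertical = az + noise(1.0),
    gyro_x = gx + noise(0.1), gyro_y = gy + noise(0.1), gyro_z = gz + noise(0.1),
    speed = pmax(speed + noise(0.05), 0),
    vertical_velocity = vz + noise(0.05),
    vertical_displacement = z + noise(0.005),
    ground_track = track + noise(0.5)
  )
  class(sensor) <- c("sensor_trace", "data.frame")
  attr(sensor, "fs") <- fs_sensor

  # insole trace ----------------------------------------------------------------
  bw_n <- profile$body_weight * GRAVITY
  ratio <- fs_sensor / fs_insole
  idx50 <- seq(1L, n, by = ratio)
  contact_l <- force_l > 0
  contact_r <- force_r > 0
  insole <- data.frame(
    t = t[idx50],
    vgrf_left = apply_insole_artifacts(
      force_l[idx50] * bw_n, contact_l[idx50], profile$body_weight,
      artifact_scale = profile$insole_swing_artifact_scale,
      area_cm2 = profile$insole_area_cm2),
    vgrf_right = apply_insole_artifacts(
      force_r[idx50] * bw_n, contact_r[idx50], profile$body_weight,
      artifact_scale = profile$insole_swing_artifact_scale,
      area_cm2 = profile$insole_area_cm2)
  )
  class(insole) <- c("insole_trace", "data.frame")
  attr(insole, "fs") <- fs_insole

  # stride table + per-stride truth ---------------------------------------------
  start_idx <- round(t_start * fs_sensor)            # 0-based, half-open
  end_idx <- round((t_start + plan$stride_duration) * fs_sensor)
  strides <- data.frame(start_idx = start_idx, end_idx = end_idx,
                        mode = plan$mode,
                        duration = plan$stride_duration)
  class(strides) <- c("stride_table", "data.frame")

  truth_targets <- do.call(rbind, lapply(seq_len(n_str), function(i) {
    sl <- (start_idx[i] + 1L):end_idx[i]
    tg <- targets_from_forces(t[sl] - t[sl[1L]],
                              force_l[sl] * bw_n, force_r[sl] * bw_n,
                              body_weight = profile$body_weight,
                              contact_threshold = 1e-9)
    cbind(data.frame(stride = i, mode = plan$mode[i], speed = plan$speed[i],
                     stride_duration = plan$stride_duration[i],
                     peak_bw_drawn = peak[i], gct_planned = gct[i]), tg)
  }))

  truth <- list(
    targets = truth_targets,
    force_left_bw = force_l, force_right_bw = force_r,
    contact_left = contact_l, contact_right = contact_r,
    contact_left_50 = contact_l[idx50], contact_right_50 = contact_r[idx50],
    jump_times = jump_times,
    gait_interval = c(pre, gait_end)
  )

  structure(list(sensor = sensor, insole = insole, strides = strides,
                 truth = truth, profile = profile, plan = plan,
                 fs_sensor = fs_sensor, fs_insole = fs_insole, seed = seed),
            class = "gait_session")
}

#' @export
print.gait_session <- function(x, ...) {
  cat(sprintf("<gait_session> %d strides (%d walk, %d run), %.1f s @ %g/%g Hz\n",
              nrow(x$strides), sum(x$strides$mode == "walk"),
              sum(x$strides$mode == "run"),
              nrow(x$sensor) / x$fs_sensor, x$fs_sensor, x$fs_insole))
  invisible(x)
}
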