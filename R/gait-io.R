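# Session I/O, insole/sensor clock synchronization via jump spikes, and
# stride segmentation from the torso sensor stream.

SENSOR_CHANNELS <- c("t", "accel_forward", "accel_lateral", "accel_vertical",
                     "gyro_x", "gyro_y", "gyro_z", "speed",
                     "vertical_velocity", "vertical_displacement",
                     "ground_track")
INSOLE_CHANNELS <- c("t", "vgrf_left", "vgrf_right")

validate_rate <- function(t, what, tol = 1e-3) {
  if (length(t) < 2L) stopf("%s trace too short", what)
  d <- diff(t)
  fs <- 1 / stats::median(d)
  if (any(abs(d - 1 / fs) > tol / fs))
    stopf("schema error: %s trace is not uniformly sampled", what)
  fs
}

validate_trace <- function(df, channels, what, expected_fs = NULL) {
  miss <- setdiff(channels, names(df))
  if (length(miss))
    stopf("schema error: %s trace lacks columns %s", what,
          paste(miss, collapse = ", "))
  bad <- channels[vapply(channels, function(ch) anyNA(df[[ch]]), logical(1))]
  if (length(bad))
    stopf("data error: NaN/NA values in %s channels: %s", what,
          paste(bad, collapse = ", "))
  fs <- validate_rate(df$t, what)
  if (!is.null(expected_fs) && abs(fs - expected_fs) > 0.001 * expected_fs)
    stopf("schema error: %s sampled at %.2f Hz, expected %g Hz", what, fs,
          expected_fs)
  attr(df, "fs") <- round(fs)
  df
}

#' Write a session to disk (CSV)
#'
#' One CSV per stream (`<stem>_sensor.csv`, `<stem>_insole.csv`, optionally
#' `<stem>_strides.csv` and `<stem>_truth.csv`) plus a YAML sidecar
#' `<stem>.yaml` recording the sampling rates. Columns are named exactly as
#' the trace fields.
#'
#' @param session a `gait_session` (or a list with at least `sensor`)
#' @param stem output path stem (no extension)
#' @export
write_session <- function(session, stem) {
  utils::write.csv(session$sensor, paste0(stem, "_sensor.csv"),
                   row.names = FALSE)
  meta <- list(fs_sensor = session$fs_sensor %||% attr(session$sensor, "fs"))
  if (!is.null(session$insole)) {
    utils::write.csv(session$insole, paste0(stem, "_insole.csv"),
                     row.names = FALSE)
    meta$fs_insole <- session$fs_insole %||% attr(session$insole, "fs")
  }
  if (!is.null(session$strides))
    utils::write.csv(session$strides, paste0(stem, "_strides.csv"),
                     row.names = FALSE)
  if (!is.null(session$truth$targets))
    utils::write.csv(session$truth$targets, paste0(stem, "_truth.csv"),
                     row.names = FALSE)
  yaml::write_yaml(meta, paste0(stem, ".yaml"))
  invisible(stem)
}

#' Read a session from disk (CSV)
#'
#' Reads the files written by [write_session()] and validates the schema:
#' uniform sampling at the recorded rates and complete channels (NA values
#' are a data error naming the offending channels).
#'
#' @param stem path stem used at write time
#' @param format on-disk format; `"csv"` is the supported format
#' @return list with `sensor`, `insole` (NULL if absent), `strides` (NULL if
#'   absent), `fs_sensor`, `fs_insole`
#' @export
read_session <- function(stem, format = "csv") {
  format <- match.arg(format, "csv")
  f_sensor <- paste0(stem, "_sensor.csv")
  if (!file.exists(f_sensor)) stopf("no sensor file at %s", f_sensor)
  meta <- if (file.exists(paste0(stem, ".yaml"))) {
    yaml::read_yaml(paste0(stem, ".yaml"))
  } else list()
  sensor <- utils::read.csv(f_sensor)
  sensor <- validate_trace(sensor, SENSOR_CHANNELS, "sensor", meta$fs_sensor)
  class(sensor) <- c("sensor_trace", "data.frame")
  insole <- NULL
  if (file.exists(paste0(stem, "_insole.csv"))) {
    insole <- utils::read.csv(paste0(stem, "_insole.csv"))
    insole <- validate_trace(insole, INSOLE_CHANNELS, "insole", meta$fs_insole)
    if (any(insole$vgrf_left < 0) || any(insole$vgrf_right < 0))
      stopf("data error: negative insole forces")
    class(insole) <- c("insole_trace", "data.frame")
  }
  strides <- NULL
  if (file.exists(paste0(stem, "_strides.csv"))) {
    strides <- utils::read.csv(paste0(stem, "_strides.csv"))
    class(strides) <- c("stride_table", "data.frame")
  }
  list(sensor = sensor, insole = insole, strides = strides,
       fs_sensor = attr(sensor, "fs"),
       fs_insole = if (is.null(insole)) NULL else attr(insole, "fs"))
}

#' Synchronize insole and sensor clocks via jump spikes
#'
#' Recordings are book-ended by two-footed jumps that produce sharp
#' co-occurring spikes in the insole's total vGRF and the sensor's vertical
#' velocity. The offset is estimated by pairing the leading (and, when
#' present, trailing) spikes of the two streams; spike times are refined by
#' parabolic interpolation around the sample peak. With two pairs, the linear
#' drift between the clocks is also estimated.
#'
#' @param sensor a `sensor_trace`
#' @param insole an `insole_trace`
#' @param body_weight subject mass in kg (sets the force spike threshold)
#' @param force_min_bw minimum total-force spike height, xBW
#' @param vz_min minimum vertical-velocity spike height, m/s
#' @return the clock offset in seconds (insole time minus sensor time at the
#'   leading jump), with attributes `drift_rate` (s/s, 0 for a single pair)
#'   and `pairs` (matrix of matched spike times)
#' @export
synchronize_traces <- function(sensor, insole, body_weight = 72,
                               force_min_bw = 3.0, vz_min = 1.2) {
  fs_s <- attr(sensor, "fs") %||% validate_rate(sensor$t, "sensor")
  fs_i <- attr(insole, "fs") %||% validate_rate(insole$t, "insole")
  refine <- function(t, x, i) {
    if (i <= 1L || i >= length(x)) return(t[i])
    num <- x[i - 1L] - x[i + 1L]
    den <- x[i - 1L] - 2 * x[i] + x[i + 1L]
    if (abs(den) < 1e-12) return(t[i])
    t[i] + 0.5 * num / den * (t[2] - t[1])
  }
  total <- insole$vgrf_left + insole$vgrf_right
  thr_f <- force_min_bw * body_weight * GRAVITY
  pk_i <- find_peaks(total, min_height = thr_f, min_spacing = round(2 * fs_i))
  vz <- lowpass(sensor$vertical_velocity, min(20, fs_s / 2.5), fs_s)
  pk_s <- find_peaks(vz, min_height = vz_min, min_spacing = round(2 * fs_s))
  if (!length(pk_i) || !length(pk_s))
    stopf("no-sync: no jump spike above the prominence threshold in %s",
          if (!length(pk_i)) "the insole trace" else "the sensor trace")
  t_i <- vapply(pk_i, function(i) refine(insole$t, total, i), numeric(1))
  t_s <- vapply(pk_s, function(i) refine(sensor$t, vz, i), numeric(1))
  k <- min(length(t_i), length(t_s))
  pairs <- cbind(sensor = c(t_s[1L], t_s[length(t_s)])[seq_len(min(k, 2L))],
                 insole = c(t_i[1L], t_i[length(t_i)])[seq_len(min(k, 2L))])
  d <- pairs[, "insole"] - pairs[, "sensor"]
  offset <- d[1L]
  drift <- if (nrow(pairs) == 2L && diff(pairs[, "sensor"]) > 1) {
    (d[2L] - d[1L]) / diff(pairs[, "sensor"])
  } else 0
  structure(offset, drift_rate = drift, pairs = pairs)
}

#' Segment a sensor trace into strides at left touch-down events
#'
#' Left touch-downs are detected as prominent peaks of the 20 Hz low-passed
#' vertical acceleration, refined to the nearest zero crossing of the
#' low-passed vertical velocity, gated to moving intervals (speed above
#' `min_speed`) and to samples where the low-passed mediolateral sway is
#' positive (the sway oscillates at the full-stride period, so its sign
#' separates left from right steps), with a minimum spacing of
#' `min_spacing` seconds. Strides run half-open from one detected left
#' touch-down to the next; a stationary input yields an empty table.
#'
#' Stride mode is labelled from the per-stride peak-to-peak vertical
#' displacement (running bounces higher than walking).
#'
#' @param sensor a `sensor_trace`
#' @param min_speed moving-floor speed, m/s
#' @param min_spacing minimum inter-stride spacing, s
#' @param lp_accel low-pass cutoff for the vertical acceleration, Hz
#' @param min_peak_height minimum touch-down peak height of the filtered
#'   vertical acceleration above gravity, m/s2
#' @param mode_disp_threshold vertical displacement p-p separating walk from
#'   run labels, m
#' @return a `stride_table` data.frame with 0-based half-open `start_idx`,
#'   `end_idx`, `mode`, `duration`
#' @export
segment_strides <- function(sensor, min_speed = 0.3, min_spacing = 0.4,
                            lp_accel = 20, min_peak_height = 1.0,
                            mode_disp_threshold = 0.071) {
  fs <- attr(sensor, "fs") %||% round(validate_rate(sensor$t, "sensor"))
  n <- nrow(sensor)
  if (n < 2 * fs) stopf("need at least 2 s of data")
  az <- lowpass(sensor$accel_vertical, min(lp_accel, fs / 2.5), fs)
  vz <- lowpass(sensor$vertical_velocity, min(10, fs / 2.5), fs)
  sway <- lowpass(sensor$accel_lateral, min(5, fs / 2.5), fs)
  moving <- lowpass(sensor$speed, min(2, fs / 2.5), fs) > min_speed
  if (!any(moving)) return(empty_stride_table())

  cand <- find_peaks(az, min_height = GRAVITY + min_peak_height,
                     min_spacing = round(min_spacing * fs / 2))
  cand <- cand[moving[cand] & sway[cand] > 0]
  if (length(cand) < 2L) return(empty_stride_table())
  # refine to the nearest vertical-velocity zero crossing
  half_win <- as.integer(round(0.1 * fs))
  cand <- vapply(cand, function(i) {
    lo <- max(2L, i - half_win); hi <- min(n, i + half_win)
    zc <- which(diff(sign(vz[lo:hi])) != 0)
    if (!length(zc)) return(i)
    zc <- zc + lo - 1L
    zc[which.min(abs(zc - i))]
  }, integer(1))
  cand <- sort(unique(cand))
  # enforce full min spacing after refinement
  keep <- cand[1L]
  for (i in cand[-1L]) if (i - keep[length(keep)] >= min_spacing * fs)
    keep <- c(keep, i)
  if (length(keep) < 2L) return(empty_stride_table())

  start_idx <- keep[-length(keep)] - 1L         # 0-based
  end_idx <- keep[-1L] - 1L
  disp_pp <- vapply(seq_along(start_idx), function(k) {
    sl <- (start_idx[k] + 1L):end_idx[k]
    diff(range(sensor$vertical_displacement[sl]))
  }, numeric(1))
  out <- data.frame(start_idx = start_idx, end_idx = end_idx,
                    mode = ifelse(disp_pp > mode_disp_threshold, "run", "walk"),
                    duration = (end_idx - start_idx) / fs)
  class(out) <- c("stride_table", "data.frame")
  out
}

empty_stride_table <- function() {
  out <- data.frame(start_idx = integer(0), end_idx = integer(0),
                    mode = character(0), duration = numeric(0))
  class(out) <- c("stride_table", "data.frame")
  out
}

#' Slice the insole trace for one stride
#'
#' Maps a stride's half-open sensor-sample window through the clock offset to
#' the insole grid, resolving boundaries by the nearest-sample rule.
#'
#' @param insole an `insole_trace`
#' @param stride one row of a `stride_table` (0-based half-open indices at
#'   the sensor rate)
#' @param offset insole-minus-sensor clock offset, s
#' @param fs_sensor sensor rate, Hz
#' @return data.frame `t` (seconds from stride start, sensor clock),
#'   `vgrf_left`, `vgrf_right`
#' @export
slice_insole <- function(insole, stride, offset = 0, fs_sensor = 400) {
  fs_i <- attr(insole, "fs") %||% round(validate_rate(insole$t, "insole"))
  t0_i <- insole$t[1L]
  t_start <- stride$start_idx / fs_sensor
  t_end <- stride$end_idx / fs_sensor
  i0 <- round((t_start + offset - t0_i) * fs_i)       # 0-based nearest sample
  i1 <- round((t_end + offset - t0_i) * fs_i)
  if (i0 < 0 || i1 > nrow(insole))
    stopf("coverage error: stride [%.2f, %.2f) s outside the insole record",
          t_start, t_end)
  rows <- (i0 + 1L):i1
  data.frame(t = insole$t[rows] - offset - t_start,
             vgrf_left = insole$vgrf_left[rows],
             vgrf_right = insole$vgrf_right[rows])
}
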