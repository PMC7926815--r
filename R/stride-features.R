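# Per-stride input features (torso sensor) and target gait parameters
# (insole force reference).

#' The canonical 27-feature table
#'
#' The per-stride input feature set is fixed here, in canonical order: for
#' each of the seven sensor channels speed, forward/lateral/vertical
#' acceleration, vertical velocity, vertical displacement and ground track,
#' the per-stride mean, peak-to-peak range (p-p, max minus min) and standard
#' deviation (SD); plus six scalars: stride duration, step length, cadence,
#' maximum speed, minimum vertical displacement and the absolute ground-track
#' change over the stride. p-p variants precede SD variants in the canonical
#' order, which feeds the tie-break of the correlation-based pruning.
#'
#' @return character vector of the 27 feature names, canonical order
#' @export
feature_names <- function() {
  chans <- c("speed", "accel_forward", "accel_lateral", "accel_vertical",
             "vertical_velocity", "vertical_displacement", "ground_track")
  c(as.vector(t(outer(chans, c("mean", "pp", "sd"), paste, sep = "_"))),
    "stride_duration", "step_length", "cadence", "speed_max",
    "vertical_displacement_min", "ground_track_abs_change")
}

#' Names of the 12 per-stride target gait parameters
#' @param normalized also include the body-weight-normalized force variants
#' @export
target_names <- function(normalized = FALSE) {
  base <- c("TDL", "TOL", "GCTL", "peak_vgrfL", "impulseL",
            "TDR", "TOR", "GCTR", "peak_vgrfR", "impulseR",
            "flight_time", "double_support_time")
  if (normalized)
    c(base, "peak_vgrfL_bw", "peak_vgrfR_bw", "impulseL_bw", "impulseR_bw")
  else base
}

#' Extract the 27 input features from one stride's sensor slice
#'
#' @param sensor_slice data.frame holding the sensor channels of one stride
#'   (columns as in a `sensor_trace`)
#' @param stride_duration stride duration in s
#' @param step_length_method `"speed"` (mean speed times step time) or
#'   `"path"` (integrated speed over the stride, halved); both use the speed
#'   channel, differing only in quadrature
#' @return one-row data.frame with the 27 features of [feature_names()]
#' @export
extract_features <- function(sensor_slice, stride_duration,
                             step_length_method = c("speed", "path")) {
  step_length_method <- match.arg(step_length_method)
  if (nrow(sensor_slice) < 10L)
    stopf("degenerate stride: slice has %d samples (< 10)", nrow(sensor_slice))
  if (!(stride_duration > 0)) stopf("stride_duration must be positive")
  chans <- c("speed", "accel_forward", "accel_lateral", "accel_vertical",
             "vertical_velocity", "vertical_displacement", "ground_track")
  missing_ch <- setdiff(chans, names(sensor_slice))
  if (length(missing_ch))
    stopf("sensor slice lacks channels: %s", paste(missing_ch, collapse = ", "))
  out <- list()
  for (ch in chans) {
    x <- sensor_slice[[ch]]
    if (anyNA(x)) stopf("channel %s contains NA", ch)
    out[[paste0(ch, "_mean")]] <- mean(x)
    out[[paste0(ch, "_pp")]] <- max(x) - min(x)
    out[[paste0(ch, "_sd")]] <- stats::sd(x)
  }
  sp <- sensor_slice$speed
  out$stride_duration <- stride_duration
  out$step_length <- if (step_length_method == "speed") {
    mean(sp) * stride_duration / 2
  } else {
    tt <- seq(0, stride_duration, length.out = length(sp))
    trapz(tt, sp) / 2
  }
  out$cadence <- 2 / stride_duration
  out$speed_max <- max(sp)
  out$vertical_displacement_min <- min(sensor_slice$vertical_displacement)
  out$ground_track_abs_change <-
    abs(sensor_slice$ground_track[nrow(sensor_slice)] - sensor_slice$ground_track[1L])
  df <- as.data.frame(out)
  df[, feature_names(), drop = FALSE]
}

# Shared target computation from aligned per-foot force vectors over one
# stride window. Times are relative to the stride start; TD is the first
# rising edge of a foot's contact signal and TO its first falling edge, so
# that in walking the right foot's toe-off (end of the stance carried over
# from the previous stride) precedes its touch-down. GCT is the total
# within-stride contact measure, which equals TO - TD whenever the stance is
# contiguous inside the stride.
targets_from_forces <- function(t_rel, force_left, force_right, body_weight,
                                contact_threshold) {
  bw_n <- body_weight * GRAVITY
  dt <- if (length(t_rel) > 1L) stats::median(diff(t_rel)) else 0
  one_foot <- function(f) {
    contact <- f > contact_threshold
    if (!any(contact)) {
      return(list(td = NA_real_, to = NA_real_, gct = 0,
                  peak = 0, impulse = 0, zero_contact = TRUE))
    }
    rises <- crossing_times(t_rel, f, contact_threshold, "rising")
    falls <- crossing_times(t_rel, f, contact_threshold, "falling")
    if (contact[1L]) {
      # stride opens mid-stance (carryover): TO ends it; TD starts the new one
      to <- if (length(falls)) falls[1L] else t_rel[length(t_rel)]
      td <- if (length(rises)) rises[1L] else t_rel[1L]
    } else {
      td <- rises[1L]
      later_falls <- falls[falls > td]
      to <- if (length(later_falls)) later_falls[1L] else t_rel[length(t_rel)]
    }
    list(td = td, to = to, gct = sum(contact) * dt,
         peak = max(f), impulse = trapz(t_rel, ifelse(contact, f, 0)),
         zero_contact = FALSE)
  }
  L <- one_foot(force_left); R <- one_foot(force_right)
  both <- (force_left > contact_threshold) & (force_right > contact_threshold)
  neither <- (force_left <= contact_threshold) & (force_right <= contact_threshold)
  df <- data.frame(
    TDL = L$td, TOL = L$to, GCTL = L$gct,
    peak_vgrfL = L$peak, impulseL = L$impulse,
    TDR = R$td, TOR = R$to, GCTR = R$gct,
    peak_vgrfR = R$peak, impulseR = R$impulse,
    flight_time = sum(neither) * dt,
    double_support_time = sum(both) * dt,
    peak_vgrfL_bw = L$peak / bw_n, peak_vgrfR_bw = R$peak / bw_n,
    impulseL_bw = L$impulse / bw_n, impulseR_bw = R$impulse / bw_n
  )
  attr(df, "zero_contact") <- c(left = L$zero_contact, right = R$zero_contact)
  df
}

#' Extract the target gait parameters from one stride's insole slice
#'
#' Touch-down (TD) and toe-off (TO) are the linearly interpolated crossings
#' of `contact_threshold`, reported in seconds relative to the stride start;
#' GCT is the within-stride contact measure per foot; peak vGRF is the
#' maximum force, impulse the trapezoidal force integral over the stance.
#' Double-support time measures samples where both feet exceed the threshold,
#' flight time where neither does. Body-weight-normalized variants divide
#' forces and impulses by `body_weight * g`.
#'
#' A foot that never exceeds the threshold yields GCT 0 and NA event times,
#' with a warning (zero-contact flag), not an error.
#'
#' @param insole_slice data.frame with columns `t` (s, relative or absolute),
#'   `vgrf_left`, `vgrf_right` (N) covering one stride
#' @param body_weight subject mass, kg, > 0
#' @param contact_threshold contact force threshold in N; default 2% of body
#'   weight
#' @return one-row data.frame with the columns of
#'   `target_names(normalized = TRUE)`
#' @export
extract_targets <- function(insole_slice, body_weight,
                            contact_threshold = 0.02 * body_weight * GRAVITY) {
  stopifnot(body_weight > 0)
  need <- c("t", "vgrf_left", "vgrf_right")
  if (!all(need %in% names(insole_slice)))
    stopf("insole slice needs columns: %s", paste(need, collapse = ", "))
  t_rel <- insole_slice$t - insole_slice$t[1L]
  tg <- targets_from_forces(t_rel, insole_slice$vgrf_left,
                            insole_slice$vgrf_right,
                            body_weight, contact_threshold)
  zc <- attr(tg, "zero_contact")
  if (any(zc))
    warnf("zero-contact stride: %s foot never exceeded the contact threshold",
          paste(names(zc)[zc], collapse = " and "))
  tg
}

#' Extract feature and target tables for every stride of a session
#'
#' Convenience wrapper looping [extract_features()] and [extract_targets()]
#' over a stride table, slicing the insole trace through the clock offset.
#'
#' @param sensor a `sensor_trace`
#' @param insole an `insole_trace` (or NULL to skip targets)
#' @param strides a `stride_table` (0-based half-open `start_idx`/`end_idx`)
#' @param body_weight subject mass, kg
#' @param offset insole-minus-sensor clock offset, s (see
#'   [synchronize_traces()])
#' @param fs_sensor sensor rate, Hz
#' @return list with data.frames `features` and `targets` (NULL if no insole)
#' @export
extract_session <- function(sensor, insole, strides, body_weight, offset = 0,
                            fs_sensor = attr(sensor, "fs") %||% 400) {
  feats <- vector("list", nrow(strides))
  targs <- if (is.null(insole)) NULL else vector("list", nrow(strides))
  for (i in seq_len(nrow(strides))) {
    sl <- (strides$start_idx[i] + 1L):strides$end_idx[i]
    feats[[i]] <- extract_features(sensor[sl, , drop = FALSE],
                                   strides$duration[i])
    if (!is.null(insole)) {
      seg <- slice_insole(insole, strides[i, ], offset, fs_sensor)
      targs[[i]] <- suppressWarnings(extract_targets(seg, body_weight))
    }
  }
  list(features = do.call(rbind, feats),
       targets = if (is.null(insole)) NULL else do.call(rbind, targs))
}
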