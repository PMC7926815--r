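# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

GRAVITY <- 9.81  # m/s^2, used for BW <-> newton conversion and kinematic consistency

#' Trapezoidal integral of y over t
#' @noRd
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}

#' Local maxima of a numeric vector above a height, with greedy spacing
#'
#' Peaks are strict local maxima; candidates are accepted in decreasing height
#' order, discarding any within `min_spacing` samples of an accepted peak.
#' @return integer sample indices (1-based), sorted ascending
#' @noRd
find_peaks <- function(x, min_height = -Inf, min_spacing = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  idx <- idx[x[idx] >= min_height]
  if (!length(idx)) return(integer(0))
  idx <- idx[order(x[idx], decreasing = TRUE)]
  kept <- integer(0)
  for (i in idx) {
    if (!length(kept) || all(abs(kept - i) >= min_spacing)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Zero-phase low-pass Butterworth filter
#' @noRd
lowpass <- function(x, cutoff_hz, fs, order = 4L) {
  w <- cutoff_hz / (fs / 2)
  if (w >= 1) return(x)
  bf <- signal::butter(order, w, type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Linearly interpolated threshold-crossing times
#'
#' Returns times where y crosses `thr` upward (rising) or downward (falling).
#' @noRd
crossing_times <- function(t, y, thr, direction = c("rising", "falling")) {
  direction <- match.arg(direction)
  above <- y > thr
  n <- length(y)
  if (n < 2L) return(numeric(0))
  if (direction == "rising") {
    i <- which(!above[-n] & above[-1])
  } else {
    i <- which(above[-n] & !above[-1])
  }
  if (!length(i)) return(numeric(0))
  frac <- (thr - y[i]) / (y[i + 1L] - y[i])
  frac[!is.finite(frac)] <- 0.5
  t[i] + frac * (t[i + 1L] - t[i])
}

#' Contiguous runs of TRUE in a logical vector
#' @return data.frame(start, end) of 1-based inclusive indices
#' @noRd
true_runs <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
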