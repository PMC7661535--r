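#' Processed PPG signal container
#'
#' A uniformly sampled PPG trace with its average sampling frequency and the
#' time of its first sample. The `stage` tag records how far along the
#' preprocessing chain (raw -> detrended -> demodulated) the values are.
#'
#' @param values numeric vector of signal values (finite).
#' @param sf average sampling frequency in samples/second (> 0).
#' @param t0 time of the first sample, seconds.
#' @param stage one of `"raw"`, `"detrended"`, `"demodulated"`.
#' @return An object of class `ppg_signal`.
#' @export
ppg_signal <- function(values, sf, t0 = 0, stage = "raw") {
  stage <- match.arg(stage, c("raw", "detrended", "demodulated"))
  if (!is.numeric(values) || length(values) < 2L)
    stop("`values` must be a numeric vector of length >= 2")
  if (!all(is.finite(values))) stop("`values` must be finite")
  if (!is.numeric(sf) || length(sf) != 1L || sf <= 0)
    stop("`sf` must be a positive scalar")
  structure(list(values = values, sf = sf, t0 = t0, stage = stage),
            class = "ppg_signal")
}

#' @export
print.ppg_signal <- function(x, ...) {
  cat(sprintf("<ppg_signal> stage=%s  n=%d  sf=%.3f Hz  t0=%.3f s\n",
              x$stage, length(x$values), x$sf, x$t0))
  invisible(x)
}

#' Sample times of a uniform signal
#' @param signal a [ppg_signal].
#' @return numeric vector `t0 + (0:(n-1))/sf`.
#' @export
signal_times <- function(signal) {
  signal$t0 + (seq_along(signal$values) - 1) / signal$sf
}

#' Average sampling frequency from timestamps
#'
#' sf = (n - 1) / (t_last - t_first): the mean rate over the whole record,
#' used to size every moving-average window downstream.
#'
#' @param time numeric vector of strictly increasing timestamps (seconds),
#'   length >= 2.
#' @return sampling frequency, samples/second.
#' @export
estimate_sampling_frequency <- function(time) {
  if (length(time) < 2L) stop("need at least 2 timestamps")
  if (any(diff(time) <= 0)) stop("timestamps must be strictly increasing")
  span <- time[length(time)] - time[1L]
  if (span <= 0) stop("timestamp span is zero")
  (length(time) - 1) / span
}

#' Resample onto a uniform grid
#'
#' Linear interpolation of (time, values) onto the grid `t0 + k/sf` spanning
#' the original time range. Linear interpolation is used because it cannot
#' overshoot, so monotone segments stay monotone.
#'
#' @param time strictly increasing timestamps (seconds).
#' @param values signal values, same length as `time`.
#' @param sf target sampling frequency (defaults to
#'   [estimate_sampling_frequency]).
#' @return a [ppg_signal] with stage `"raw"`.
#' @export
resample_uniform <- function(time, values, sf = estimate_sampling_frequency(time)) {
  if (length(time) != length(values)) stop("`time` and `values` lengths differ")
  if (any(diff(time) <= 0)) stop("timestamps must be strictly increasing")
  grid <- seq(time[1L], time[length(time)], by = 1 / sf)
  out <- approx(time, values, xout = grid, method = "linear")$y
  ppg_signal(out, sf = sf, t0 = time[1L], stage = "raw")
}

# force an integer window length to be odd so the average is centered
.odd_window <- function(w) {
  w <- as.integer(round(w))
  if (w < 1L) w <- 1L
  if (w %% 2L == 0L) w <- w + 1L
  w
}

#' Centered moving average
#'
#' Sliding mean over a symmetric window of `window` samples (forced odd so
#' the window is centered). Near the edges the window is truncated to the
#' available samples, so the output has the same length as the input and no
#' values are fabricated beyond the record.
#'
#' @param values numeric vector.
#' @param window window length in samples (>= 1; incremented to odd if even).
#' @return numeric vector, same length as `values`.
#' @examples
#' centered_moving_average(c(1, 2, 3, 4, 5), 3) # 1.5 2 3 4 4.5
#' @export
centered_moving_average <- function(values, window) {
  n <- length(values)
  window <- .odd_window(window)
  if (window > n) stop("window longer than signal")
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, values))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detrend by subtracting a one-second centered moving average
#'
#' Subtracting the CMA with a window of one second (round(sf) samples) acts
#' as a high-pass filter: baseline drift slower than the heart beat is
#' removed while the pulsatile component passes essentially unchanged.
#'
#' @param signal a [ppg_signal] with stage `"raw"`.
#' @return a [ppg_signal] with stage `"detrended"`, mean approximately 0.
#' @export
detrend <- function(signal) {
  stopifnot(inherits(signal, "ppg_signal"))
  w <- .odd_window(signal$sf)
  if (length(signal$values) <= w) stop("signal shorter than the detrending window")
  out <- signal$values - centered_moving_average(signal$values, w)
  ppg_signal(out, sf = signal$sf, t0 = signal$t0, stage = "detrended")
}

# analytic signal s + i*H(s) via the frequency-domain construction
.analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous-amplitude envelope of a signal
#'
#' Modulus of the analytic signal `s + iH(s)` where `H` is the Hilbert
#' transform, computed by the standard frequency-domain construction on the
#' full record.
#'
#' @param values numeric vector.
#' @return envelope, same length.
#' @export
signal_envelope <- function(values) {
  Mod(.analytic_signal(values))
}

#' Demodulate a detrended PPG signal
#'
#' The envelope (instantaneous amplitude) is estimated from the analytic
#' signal, smoothed with a one-second centered moving average, and the
#' detrended signal is divided by it. The division is guarded by a relative
#' floor (1e-3 of the envelope maximum) so flat or silent stretches cannot
#' blow up; samples where the floor engaged are reported in the
#' `floored` attribute.
#'
#' @param signal a [ppg_signal] with stage `"detrended"`.
#' @return a [ppg_signal] with stage `"demodulated"` and attribute
#'   `floored` (integer indices where the envelope floor was active).
#' @export
demodulate <- function(signal) {
  stopifnot(inherits(signal, "ppg_signal"))
  if (signal$stage != "detrended")
    stop("demodulate() expects a detrended signal")
  s <- signal$values
  if (all(s == 0)) stop("degenerate all-zero signal: envelope undefined")
  env <- signal_envelope(s)
  w <- .odd_window(signal$sf)
  env_s <- centered_moving_average(env, w)
  floor_val <- max(env_s) * 1e-3
  floored <- which(env_s < floor_val)
  out <- s / pmax(env_s, floor_val)
  res <- ppg_signal(out, sf = signal$sf, t0 = signal$t0, stage = "demodulated")
  attr(res, "floored") <- floored
  res
}

#' Full preprocessing chain for a raw recording
#'
#' Deduplicates repeated timestamps (first occurrence kept), resamples the
#' red channel onto a uniform grid at the record's average sampling
#' frequency, detrends and demodulates.
#'
#' @param rec a [raw_recording].
#' @param stages if `TRUE`, return all three stages as a list instead of
#'   only the demodulated signal.
#' @return a demodulated [ppg_signal], or a list
#'   `(raw, detrended, demodulated)` when `stages = TRUE`.
#' @export
preprocess_recording <- function(rec, stages = FALSE) {
  stopifnot(inherits(rec, "raw_recording"))
  keep <- !duplicated(rec$time)
  time <- rec$time[keep]
  red <- rec$red[keep]
  sf <- estimate_sampling_frequency(time)
  raw <- resample_uniform(time, red, sf)
  det <- detrend(raw)
  dem <- demodulate(det)
  if (stages) list(raw = raw, detrended = det, demodulated = dem) else dem
}
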