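#' Detected systolic peaks
#'
#' @param indices integer sample positions of the peaks.
#' @param signal the demodulated [ppg_signal] they were detected on.
#' @return An object of class `ppg_peaks` with fields `indices`, `times`
#'   (seconds) and `heights` (signal values at the peaks).
#' @export
ppg_peaks <- function(indices, signal) {
  indices <- as.integer(indices)
  t <- signal$t0 + (indices - 1L) / signal$sf
  structure(list(indices = indices, times = t,
                 heights = signal$values[indices], sf = signal$sf),
            class = "ppg_peaks")
}

#' @export
print.ppg_peaks <- function(x, ...) {
  cat(sprintf("<ppg_peaks> %d peaks", length(x$indices)))
  if (length(x$indices) >= 2L)
    cat(sprintf("  mean RR=%.0f ms", mean(diff(x$times)) * 1000))
  cat("\n")
  invisible(x)
}

# argmax of each maximal run where values > their centered moving average;
# ties broken by the earliest index
.partial_peaks <- function(values, window) {
  cma <- centered_moving_average(values, window)
  above <- values > cma
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- integer(length(runs))
  for (j in seq_along(runs)) {
    k <- runs[j]
    seg <- starts[k]:ends[k]
    out[j] <- seg[which.max(values[seg])]
  }
  out
}

# iterative 400 ms rule: while any two candidates are closer than `min_gap`
# seconds, drop the smaller of the first offending pair (earlier kept on
# height ties), rescanning from the left until stable
.merge_close_peaks <- function(idx, values, sf, min_gap = 0.4) {
  repeat {
    if (length(idx) < 2L) return(idx)
    gaps <- diff(idx) / sf
    bad <- which(gaps < min_gap)
    if (length(bad) == 0L) return(idx)
    i <- bad[1L]
    drop <- if (values[idx[i + 1L]] > values[idx[i]]) i else i + 1L
    idx <- idx[-drop]
  }
}

#' Detect systolic peaks by six-window voting
#'
#' For each window width in (0.5, 1, 1.5, 2, 2.5, 3) times the sampling
#' frequency, the signal's centered moving average is computed, each maximal
#' run of samples strictly above it is located, and the maximum of each run
#' is labelled a partial peak. Points labelled by all six widths become
#' possible maxima; while any two possible maxima lie closer than 400 ms the
#' smaller one is discarded.
#'
#' @param signal a demodulated [ppg_signal] of length > 3*sf.
#' @return a [ppg_peaks]; empty if no point survives the vote.
#' @export
detect_peaks <- function(signal) {
  stopifnot(inherits(signal, "ppg_signal"))
  v <- signal$values
  sf <- signal$sf
  if (length(v) <= 3 * sf) stop("signal too short for peak detection (need > 3*sf samples)")
  widths <- round(c(0.5, 1, 1.5, 2, 2.5, 3) * sf)
  labelled <- lapply(widths, function(w) .partial_peaks(v, w))
  cand <- Reduce(intersect, labelled)
  cand <- sort(cand)
  keep <- .merge_close_peaks(cand, v, sf)
  ppg_peaks(keep, signal)
}

#' RR intervals from detected peaks
#'
#' @param peaks a [ppg_peaks] with at least two peaks.
#' @return numeric vector of inter-beat intervals in milliseconds,
#'   class `rr_series`.
#' @export
rr_intervals <- function(peaks) {
  stopifnot(inherits(peaks, "ppg_peaks"))
  if (length(peaks$times) < 2L) stop("need at least 2 peaks for RR intervals")
  structure(diff(peaks$times) * 1000, class = "rr_series")
}

# signal minimum between each pair of consecutive peaks (the matched
# valleys); earliest index on ties
.peak_valleys <- function(values, idx) {
  if (length(idx) < 2L) return(integer(0))
  vapply(seq_len(length(idx) - 1L), function(k) {
    seg <- idx[k]:idx[k + 1L]
    seg[which.min(values[seg])]
  }, integer(1))
}

# count strict local extrema; plateau runs of equal values count once,
# at their first index
.count_local_extrema <- function(values) {
  r <- rle(values)
  v <- r$values
  m <- length(v)
  if (m < 3L) return(0L)
  interior <- 2L:(m - 1L)
  is_max <- v[interior] > v[interior - 1L] & v[interior] > v[interior + 1L]
  is_min <- v[interior] < v[interior - 1L] & v[interior] < v[interior + 1L]
  sum(is_max) + sum(is_min)
}

#' Quality-score arithmetic
#'
#' The bare Q expression:
#' `variance * (n_extrema - n_detected + 2) / n_points`.
#' Exposed separately so the arithmetic can be audited against hand-worked
#' cases independently of peak and extrema counting.
#'
#' @param variance sample variance of the detected peak heights.
#' @param n_extrema number of strict local extrema in the signal.
#' @param n_detected number of detected peaks plus matched valleys.
#' @param n_points signal length in samples.
#' @return Q.
#' @export
quality_q <- function(variance, n_extrema, n_detected, n_points) {
  variance * (n_extrema - n_detected + 2) / n_points
}

#' Signal-quality score
#'
#' Q = Var(detected peak heights) * (N_extrema - N_detected + 2) / N_points,
#' where N_extrema counts all strict local extrema of the signal,
#' N_detected counts the detected peaks plus their matched valleys (the
#' signal minimum between each consecutive peak pair), and N_points is the
#' signal length. The +2 keeps the count factor positive when a terminal
#' peak has no valley on one side. 0 is the perfect score; higher is
#' noisier or worse demodulated. With fewer than two peaks the variance is
#' undefined and Q is reported as +Inf (record fails).
#'
#' @param signal the demodulated [ppg_signal].
#' @param peaks the [ppg_peaks] detected on `signal`.
#' @param threshold records pass when Q < threshold (default 0.01).
#' @return list of class `ppg_quality`: `q`, `variance_peak_heights`,
#'   `n_local_extrema`, `n_detected_extrema`, `n_points`, `passed`.
#' @export
quality_score <- function(signal, peaks, threshold = 0.01) {
  stopifnot(inherits(signal, "ppg_signal"), inherits(peaks, "ppg_peaks"))
  n_points <- length(signal$values)
  n_extrema <- .count_local_extrema(signal$values)
  np <- length(peaks$indices)
  if (np < 2L) {
    out <- list(q = Inf, variance_peak_heights = NA_real_,
                n_local_extrema = n_extrema, n_detected_extrema = np,
                n_points = n_points, passed = FALSE, threshold = threshold)
    class(out) <- "ppg_quality"
    return(out)
  }
  valleys <- .peak_valleys(signal$values, peaks$indices)
  n_detected <- np + length(valleys)
  v <- var(peaks$heights)
  q <- quality_q(v, n_extrema, n_detected, n_points)
  out <- list(q = q, variance_peak_heights = v,
              n_local_extrema = n_extrema, n_detected_extrema = n_detected,
              n_points = n_points, passed = q < threshold,
              threshold = threshold)
  class(out) <- "ppg_quality"
  out
}

#' @export
print.ppg_quality <- function(x, ...) {
  cat(sprintf("<ppg_quality> Q=%.3g  (%s at threshold %.3g)\n",
              x$q, if (x$passed) "pass" else "fail", x$threshold))
  invisible(x)
}
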