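#' Names of the 38 PPG features, in canonical order
#'
#' Three families: 9 RR-interval statistics, 7 successive-difference
#' statistics, and 22 second-derivative (SDPPG) a-e wave quantities
#' (amplitude ratios including the aging index AGI = (b - c - d - e)/a,
#' absolute amplitudes, slopes and time distances between wave pairs).
#'
#' @return character vector of length 38.
#' @export
ppg_feature_names <- function() {
  c(
    # RR family (9)
    "ibi", "medianRR", "madRR", "sdnn", "cvRR", "rangeRR", "tpr",
    "skewnessRR", "kurtosisRR",
    # RR_diff family (7)
    "sdsd", "rmssd", "pnn20", "pnn50", "tpr_diff", "skewness_diff",
    "kurtosis_diff",
    # SDPPG family (22)
    "ratio_b_a", "ratio_c_a", "ratio_d_a", "ratio_e_a", "agi",
    "a", "b", "c", "d", "e",
    "slope_ab", "slope_ac", "slope_ad", "slope_ae", "slope_bc", "slope_be",
    "t_ab", "t_ac", "t_ad", "t_ae", "t_bc", "t_be"
  )
}

#' Turning point ratio
#'
#' Number of strict interior local extrema divided by the series length; an
#' index of randomness in (0, 1): an i.i.d. continuous series has expected
#' ratio (2/3)(n-2)/n, a monotone series has 0.
#'
#' @param series numeric vector, length >= 3.
#' @return the ratio.
#' @export
turning_point_ratio <- function(series) {
  n <- length(series)
  if (n < 3L) stop("turning point ratio needs at least 3 points")
  i <- 2L:(n - 1L)
  tp <- (series[i] > series[i - 1L] & series[i] > series[i + 1L]) |
        (series[i] < series[i - 1L] & series[i] < series[i + 1L])
  sum(tp) / n
}

# moment-based skewness; 0 for zero-variance input
.skewness <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  mean((x - mean(x))^3) / m2^1.5
}

# moment-based excess kurtosis; 0 for zero-variance input
.kurtosis <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  mean((x - mean(x))^4) / m2^2 - 3
}

#' RR-interval (HRV) features
#'
#' ibi (mean inter-beat interval), medianRR, madRR (median absolute
#' deviation from the median, unscaled), sdnn (sample standard deviation),
#' cvRR (sdnn/ibi), rangeRR, tpr (turning point ratio of RR), skewnessRR
#' and kurtosisRR (moment-based; kurtosis is excess kurtosis; both 0 on
#' zero-variance input). All interval statistics are in milliseconds.
#'
#' @param rr an `rr_series` (milliseconds) with >= 4 intervals.
#' @return named numeric vector of length 9.
#' @export
rr_features <- function(rr) {
  rr <- as.numeric(rr)
  if (length(rr) < 4L) stop("rr family needs at least 4 intervals")
  c(ibi = mean(rr),
    medianRR = median(rr),
    madRR = median(abs(rr - median(rr))),
    sdnn = sd(rr),
    cvRR = sd(rr) / mean(rr),
    rangeRR = max(rr) - min(rr),
    tpr = turning_point_ratio(rr),
    skewnessRR = .skewness(rr),
    kurtosisRR = .kurtosis(rr))
}

#' Successive-difference (RR_diff) features
#'
#' RR_diff is the sequence of differences between successive RR intervals.
#' Features: sdsd (sample standard deviation of RR_diff), rmssd (root mean
#' square of RR_diff), pnn20/pnn50 (proportion of |RR_diff| strictly larger
#' than 20/50 ms), tpr_diff, skewness_diff, kurtosis_diff.
#'
#' @param rr an `rr_series` (milliseconds) with >= 4 intervals.
#' @return named numeric vector of length 7.
#' @export
rrdiff_features <- function(rr) {
  rr <- as.numeric(rr)
  if (length(rr) < 4L) stop("rr_diff family needs at least 4 intervals")
  d <- diff(rr)
  c(sdsd = sd(d),
    rmssd = sqrt(mean(d^2)),
    pnn20 = mean(abs(d) > 20),
    pnn50 = mean(abs(d) > 50),
    tpr_diff = turning_point_ratio(d),
    skewness_diff = .skewness(d),
    kurtosis_diff = .kurtosis(d))
}

# centered first difference in sample units; one-sided at the edges
.central_diff <- function(x) {
  n <- length(x)
  d <- numeric(n)
  d[1L] <- x[2L] - x[1L]
  d[n] <- x[n] - x[n - 1L]
  i <- 2L:(n - 1L)
  d[i] <- (x[i + 1L] - x[i - 1L]) / 2
  d
}

#' Second derivative of the PPG signal (SDPPG)
#'
#' The signal is lightly smoothed with a ~50 ms centered moving average
#' (finite differences amplify noise at 30 Hz; 50 ms stays below the a-b
#' wave spacing so the extrema survive), then differentiated twice by
#' centered first differences and scaled by sf^2 to physical units
#' (signal units per second squared).
#'
#' @param signal a [ppg_signal].
#' @return numeric vector, same length as the signal.
#' @export
sdppg <- function(signal) {
  stopifnot(inherits(signal, "ppg_signal"))
  v <- signal$values
  if (length(v) < 7L) stop("signal too short for second differentiation")
  # ceiling, not round: 0.05*sf sits on the .5 rounding boundary at 30 Hz,
  # where round() would flip the window between 1 and 3 with the third
  # decimal of the estimated sf
  w <- .odd_window(ceiling(0.05 * signal$sf))
  s <- centered_moving_average(v, w)
  .central_diff(.central_diff(s)) * signal$sf^2
}

# fourth derivative (unscaled): two further centered differences of SDPPG;
# only its zero crossings are used
.fdppg <- function(sd2) {
  .central_diff(.central_diff(sd2))
}

#' Locate the SDPPG fiducial waves a-e for each beat
#'
#' Beat cycle k spans from the valley preceding peak k to the valley
#' preceding peak k+1. Within a cycle the fourth derivative's zero
#' crossings mark the SDPPG inflection points (crossing placed at the left
#' sample of each sign change); between two consecutive inflection points
#' at most one SDPPG extremum can exist, found as the interior
#' maximum/minimum of the segment according to its concavity. The wave `a`
#' is the first-and-highest SDPPG maximum of the cycle; b, c, d, e are the
#' subsequent alternating minima and maxima. Beats missing any of the five
#' points, or whose `a` is not the cycle's global SDPPG maximum, are
#' flagged invalid rather than dropped.
#'
#' @param signal a demodulated [ppg_signal].
#' @param peaks the [ppg_peaks] for `signal`.
#' @return data.frame of class `ppg_fiducials`, one row per analysable
#'   beat: `beat`, index/time/value triples for a-e
#'   (`idx_a`..`idx_e`, `t_a`..`t_e`, `v_a`..`v_e`) and `valid`.
#' @export
detect_fiducials <- function(signal, peaks) {
  stopifnot(inherits(signal, "ppg_signal"), inherits(peaks, "ppg_peaks"))
  v <- signal$values
  sd2 <- sdppg(signal)
  fd4 <- .fdppg(sd2)
  idx <- peaks$indices
  np <- length(idx)
  if (np < 3L) {
    out <- as.data.frame(matrix(numeric(0), 0L, 16L))
    names(out) <- c("beat", paste0("idx_", c("a", "b", "c", "d", "e")),
                    paste0("t_", c("a", "b", "c", "d", "e")),
                    paste0("v_", c("a", "b", "c", "d", "e")))
    out$valid <- logical(0)
    class(out) <- c("ppg_fiducials", "data.frame")
    return(out)
  }
  valleys <- .peak_valleys(v, idx)   # valleys[k] lies between peaks k, k+1
  mat <- matrix(NA_real_, np - 2L, 11L)
  for (k in 2L:(np - 1L)) {
    lo <- valleys[k - 1L]            # valley preceding peak k
    hi <- valleys[k]                 # valley preceding peak k+1
    cand <- .segment_extrema(sd2, fd4, lo, hi)
    mat[k - 1L, ] <- .assign_waves(cand, sd2, lo, hi)
  }
  out <- as.data.frame(mat)
  names(out) <- c(paste0("idx_", c("a", "b", "c", "d", "e")),
                  paste0("v_", c("a", "b", "c", "d", "e")), "valid")
  out$valid <- out$valid > 0
  out$beat <- 2L:(np - 1L)
  t0 <- signal$t0
  sf <- signal$sf
  for (wv in c("a", "b", "c", "d", "e"))
    out[[paste0("t_", wv)]] <- t0 + (out[[paste0("idx_", wv)]] - 1L) / sf
  out <- out[, c("beat", paste0("idx_", c("a", "b", "c", "d", "e")),
                 paste0("t_", c("a", "b", "c", "d", "e")),
                 paste0("v_", c("a", "b", "c", "d", "e")), "valid")]
  class(out) <- c("ppg_fiducials", "data.frame")
  out
}

# candidate SDPPG extrema between consecutive FDPPG zero crossings inside
# [lo, hi]: per segment, a concave stretch (FDPPG < 0) can hold one
# maximum, a convex stretch one minimum. At 30 Hz the true extremum can
# quantize onto a segment boundary, so the only requirement kept is that
# the point be a strict local extremum of the sampled SDPPG. Returns a
# list (idx, val, is_max) ordered in time.
.segment_extrema <- function(sd2, fd4, lo, hi) {
  seg <- lo:(hi - 1L)
  cross <- seg[fd4[seg] * fd4[seg + 1L] < 0]
  idx <- integer(0)
  is_max <- logical(0)
  n <- length(sd2)
  if (length(cross) >= 2L) {
    for (j in seq_len(length(cross) - 1L)) {
      a <- cross[j] + 1L
      b <- cross[j + 1L]
      if (b <= a) next
      span <- a:b
      concave <- mean(fd4[span]) < 0
      m <- if (concave) span[which.max(sd2[span])] else span[which.min(sd2[span])]
      if (m <= 1L || m >= n) next
      strict <- if (concave)
        sd2[m] > sd2[m - 1L] && sd2[m] > sd2[m + 1L]
      else
        sd2[m] < sd2[m - 1L] && sd2[m] < sd2[m + 1L]
      if (!strict) next
      idx <- c(idx, m)
      is_max <- c(is_max, concave)
    }
  }
  keep <- !duplicated(idx)
  list(idx = idx[keep], val = sd2[idx[keep]], is_max = is_max[keep])
}

# pick a = highest maximum candidate, then b..e as the next candidate of
# alternating type after the previous wave; returns numeric vector
# (idx_a..e, v_a..e, valid)
.assign_waves <- function(cand, sd2, lo, hi) {
  na_row <- c(rep(NA_real_, 10L), 0)
  maxima <- which(cand$is_max)
  if (length(maxima) == 0L) return(na_row)
  a_pos <- maxima[which.max(cand$val[maxima])]
  pos <- c(a = a_pos)
  want <- c(b = FALSE, c = TRUE, d = FALSE, e = TRUE)
  cur <- a_pos
  for (wv in names(want)) {
    nxt <- which(seq_along(cand$idx) > cur & cand$is_max == want[[wv]])
    if (length(nxt) == 0L) return(na_row)
    cur <- nxt[1L]
    pos[wv] <- cur
  }
  # a must dominate the whole cycle's SDPPG
  valid <- cand$val[a_pos] >= max(sd2[lo:hi])
  c(cand$idx[pos], cand$val[pos], as.numeric(valid))
}

#' SDPPG a-e wave features
#'
#' Per valid beat: amplitude ratios b/a, c/a, d/a, e/a and the aging index
#' AGI = (b - c - d - e)/a; the absolute amplitudes a-e; slopes
#' (value_y - value_x)/(t_y - t_x) and time distances t_y - t_x for the
#' pairs ab, ac, ad, ae, bc, be. Aggregated across beats by the median;
#' at least 5 valid beats are required.
#'
#' @param fp a `ppg_fiducials` data.frame from [detect_fiducials].
#' @return named numeric vector of length 22.
#' @export
sdppg_features <- function(fp) {
  fp <- fp[fp$valid %in% TRUE, , drop = FALSE]
  if (nrow(fp) < 5L) stop("sdppg family needs at least 5 valid beats")
  pairs <- c("ab", "ac", "ad", "ae", "bc", "be")
  per_beat <- function(r) {
    vals <- c(a = r$v_a, b = r$v_b, c = r$v_c, d = r$v_d, e = r$v_e)
    ts <- c(a = r$t_a, b = r$t_b, c = r$t_c, d = r$t_d, e = r$t_e)
    sl <- vapply(pairs, function(p) {
      x <- substr(p, 1, 1); y <- substr(p, 2, 2)
      (vals[y] - vals[x]) / (ts[y] - ts[x])
    }, numeric(1))
    td <- vapply(pairs, function(p) {
      x <- substr(p, 1, 1); y <- substr(p, 2, 2)
      ts[y] - ts[x]
    }, numeric(1))
    c(ratio_b_a = vals[["b"]] / vals[["a"]],
      ratio_c_a = vals[["c"]] / vals[["a"]],
      ratio_d_a = vals[["d"]] / vals[["a"]],
      ratio_e_a = vals[["e"]] / vals[["a"]],
      agi = (vals[["b"]] - vals[["c"]] - vals[["d"]] - vals[["e"]]) / vals[["a"]],
      vals,
      stats::setNames(sl, paste0("slope_", pairs)),
      stats::setNames(td, paste0("t_", pairs)))
  }
  mat <- t(vapply(seq_len(nrow(fp)), function(i) per_beat(fp[i, ]), numeric(22)))
  apply(mat, 2, median)
}

#' Extract the full 38-feature vector for one recording
#'
#' Concatenates the RR family (9), the successive-difference family (7) and
#' the SDPPG family (22) in the fixed order of [ppg_feature_names].
#'
#' @param signal a demodulated [ppg_signal] that passed quality control.
#' @param peaks the [ppg_peaks] for `signal`.
#' @return named numeric vector of length 38.
#' @export
extract_features <- function(signal, peaks) {
  if (length(peaks$indices) < 5L)
    stop("rr family needs at least 4 intervals (5 peaks)")
  rr <- rr_intervals(peaks)
  out <- c(rr_features(rr), rrdiff_features(rr),
           sdppg_features(detect_fiducials(signal, peaks)))
  stopifnot(identical(names(out), ppg_feature_names()))
  out
}
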