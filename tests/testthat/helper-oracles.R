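# Independent brute-force oracles. These deliberately re-derive results by
# literal enumeration (explicit loops, no shared code with R/) so they can
# stand as references for the vectorized implementations.

# naive centered moving average: explicit loop, truncated edges, odd window
oracle_cma <- function(x, window) {
  w <- as.integer(round(window))
  if (w %% 2L == 0L) w <- w + 1L
  h <- (w - 1L) / 2L
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- mean(x[max(1L, i - h):min(n, i + h)])
  out
}

# literal six-window voting peak detector with the 400 ms rule
oracle_detect_peaks <- function(values, sf) {
  n <- length(values)
  label_sets <- list()
  for (w in round(c(0.5, 1, 1.5, 2, 2.5, 3) * sf)) {
    cma <- oracle_cma(values, w)
    labs <- integer(0)
    i <- 1L
    while (i <= n) {
      if (values[i] > cma[i]) {
        j <- i
        while (j < n && values[j + 1L] > cma[j + 1L]) j <- j + 1L
        run <- i:j
        labs <- c(labs, run[which.max(values[run])])
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
    label_sets[[length(label_sets) + 1L]] <- labs
  }
  cand <- sort(Reduce(intersect, label_sets))
  repeat {
    if (length(cand) < 2L) break
    changed <- FALSE
    for (k in seq_len(length(cand) - 1L)) {
      if ((cand[k + 1L] - cand[k]) / sf < 0.4) {
        drop <- if (values[cand[k + 1L]] > values[cand[k]]) k else k + 1L
        cand <- cand[-drop]
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  as.integer(cand)
}

# concordant-pair (Mann-Whitney) AUC by full enumeration
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# smooth-ish pseudo-PPG signals for the peak-detector equivalence checks
random_ppg_like <- function(n, sf = 30, seed = 1) {
  set.seed(seed)
  t <- (0:(n - 1)) / sf
  f <- runif(1, 0.9, 1.6)
  sin(2 * pi * f * t) + 0.3 * sin(2 * pi * 2 * f * t + runif(1, 0, 6)) +
    0.2 * rnorm(n)
}

# a clean-measurement subject (no additive noise/modulation/drift)
clean_subject <- function(seed, ...) {
  synth_subject(paste0("clean", seed), noise_amp = 0, mod_depth = 0,
                drift_amp = 0, seed = seed, ...)
}

# dense-grid a-e wave positions (cycle seconds) of a beat template,
# by direct numerical differentiation of the analytic pulse
oracle_template_waves <- function(stiffness, h = 1e-4) {
  tpl <- beat_template(stiffness)
  u <- seq(0.01, 0.99, by = h)
  f <- tpl(u)
  d2 <- diff(diff(f)) / h^2
  um <- u[2:(length(u) - 1L)]
  s <- sign(diff(d2))
  loc_max <- which(diff(s) == -2) + 1L
  loc_min <- which(diff(s) == 2) + 1L
  a <- loc_max[which.max(d2[loc_max])]
  pick_next <- function(pool, after) {
    cand <- pool[pool > after]
    if (length(cand) == 0L) stop("oracle: wave missing in template")
    cand[1L]
  }
  b <- pick_next(loc_min, a)
  cc <- pick_next(loc_max, b)
  d <- pick_next(loc_min, cc)
  e <- pick_next(loc_max, d)
  idx <- c(a = a, b = b, c = cc, d = d, e = e)
  list(u = stats::setNames(um[idx], names(idx)),
       val = stats::setNames(d2[idx], names(idx)))
}
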