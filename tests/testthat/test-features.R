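test_that("turning point ratio closed forms", {
  expect_equal(turning_point_ratio(1:50), 0)
  expect_equal(turning_point_ratio(c(5, 1, 6, 2, 7)), 0.6)
  expect_error(turning_point_ratio(c(1, 2)), "at least 3")
  set.seed(4)
  x <- runif(1e4)
  expect_equal(turning_point_ratio(x), (2 / 3) * (1e4 - 2) / 1e4,
               tolerance = 0.02)
})

test_that("RR-family hand cases and degenerate input", {
  f <- rr_features(structure(c(800, 820, 790, 810), class = "rr_series"))
  expect_equal(f[["ibi"]], 805)
  expect_equal(f[["medianRR"]], 805)
  expect_equal(f[["madRR"]], 10)
  expect_equal(f[["sdnn"]], 12.90994, tolerance = 1e-5)
  expect_equal(f[["tpr"]], 0.5)
  expect_equal(f[["cvRR"]], 12.90994 / 805, tolerance = 1e-5)
  expect_equal(f[["rangeRR"]], 30)
  cst <- rr_features(structure(rep(800, 10), class = "rr_series"))
  expect_equal(unname(cst[c("sdnn", "madRR", "tpr", "skewnessRR", "kurtosisRR")]),
               rep(0, 5))
  expect_error(rr_features(structure(c(800, 810, 820), class = "rr_series")),
               "at least 4")
})

test_that("RR-difference family hand cases", {
  rr <- structure(c(800, 820, 790, 810), class = "rr_series")  # diffs 20 -30 20
  f <- rrdiff_features(rr)
  expect_equal(f[["rmssd"]], sqrt((400 + 900 + 400) / 3), tolerance = 1e-9)
  expect_equal(f[["rmssd"]], 23.80476, tolerance = 1e-5)
  expect_equal(f[["sdsd"]], 28.86751, tolerance = 1e-5)
  expect_equal(f[["pnn20"]], 1 / 3)   # strict >, absolute value
  expect_equal(f[["pnn50"]], 0)
  cst <- rrdiff_features(structure(rep(800, 10), class = "rr_series"))
  expect_true(all(cst == 0))
  alt <- rrdiff_features(structure(rep(c(800, 900), 6), class = "rr_series"))
  expect_equal(alt[["pnn50"]], 1)
})

test_that("moment identities on random vectors", {
  set.seed(7)
  for (i in 1:10) {
    rr <- structure(800 + rnorm(30, 0, 40), class = "rr_series")
    d <- diff(as.numeric(rr))
    f <- rrdiff_features(rr)
    expect_equal(f[["rmssd"]]^2, mean(d^2))
    expect_equal(f[["sdsd"]]^2, var(d))
    g <- rr_features(rr)
    expect_true(g[["tpr"]] >= 0 && g[["tpr"]] <= 1)
    expect_gte(f[["pnn20"]], f[["pnn50"]])
  }
})

test_that("second derivative against closed forms", {
  # densely sampled sine: sdppg ~ -(2 pi f)^2 sin
  sf <- 240
  t <- seq(0, 5, by = 1 / sf)
  f <- 1.25
  sig <- ppg_signal(sin(2 * pi * f * t), sf)
  d2 <- sdppg(sig)
  interior <- 30:(length(t) - 30)
  truth <- -(2 * pi * f)^2 * sin(2 * pi * f * t)
  expect_lt(max(abs(d2[interior] - truth[interior])) / (2 * pi * f)^2, 0.05)
  # linear -> 0; quadratic -> constant 2
  lin <- sdppg(ppg_signal(3 * t + 1, sf))
  expect_lt(max(abs(lin[interior])), 1e-6)
  quad <- sdppg(ppg_signal(t^2, sf))
  expect_equal(quad[interior], rep(2, length(interior)), tolerance = 1e-6)
  expect_error(sdppg(ppg_signal(c(1, 2, 3), 30)), "too short")
})

test_that("fiducial a-e waves match the dense-grid template oracle", {
  st <- 0.45
  tr <- clean_subject(4, stiffness = st, heart_rate = 72, rsa_depth = 0,
                      rr_randomness = 0)
  rec <- generate_recording(tr)
  sig <- preprocess_recording(rec)
  pk <- detect_peaks(sig)
  fp <- detect_fiducials(sig, pk)
  expect_gt(sum(fp$valid), 20)
  oracle <- oracle_template_waves(st)
  u_peak <- attr(beat_template(st), "u_peak")
  tol <- 2 / sig$sf
  # one cycle start per beat, anchored on the a wave (earliest of the five)
  v <- fp[fp$valid, , drop = FALSE]
  starts <- vapply(v$t_a, function(x) {
    tr$true_peak_times[which.min(abs(tr$true_peak_times - x))]
  }, numeric(1)) - u_peak * 0.8
  for (wv in c("a", "b", "c", "d", "e")) {
    offs <- v[[paste0("t_", wv)]] - starts
    expect_true(all(abs(offs - oracle$u[[wv]] * 0.8) <= tol),
                label = paste("wave", wv, "within 2 samples of oracle"))
  }
})

test_that("fiducial ordering, alternation and dominance invariants", {
  for (s in 1:3) {
    tr <- synth_subject(paste0("inv", s), stiffness = 0.15 + 0.25 * s,
                        rr_randomness = 0.4, noise_amp = 0.03,
                        mod_depth = 0.3, drift_amp = 0.5, seed = 40 + s)
    sig <- preprocess_recording(generate_recording(tr))
    pk <- detect_peaks(sig)
    fp <- detect_fiducials(sig, pk)
    v <- fp[fp$valid, , drop = FALSE]
    expect_gt(nrow(v), 5)
    expect_true(all(v$t_a < v$t_b & v$t_b < v$t_c &
                    v$t_c < v$t_d & v$t_d < v$t_e))
    # alternation: a,c,e maxima over their neighbours b,d
    expect_true(all(v$v_b < v$v_a & v$v_b < v$v_c))
    expect_true(all(v$v_d < v$v_c & v$v_d < v$v_e))
    # a is the highest SDPPG value of its beat
    expect_true(all(v$v_a >= v$v_b & v$v_a >= v$v_c &
                    v$v_a >= v$v_d & v$v_a >= v$v_e))
  }
})

test_that("SDPPG feature arithmetic and aggregation", {
  beat <- data.frame(beat = 1, idx_a = 10, idx_b = 12, idx_c = 14,
                     idx_d = 16, idx_e = 18,
                     t_a = 1.00, t_b = 1.05, t_c = 1.10, t_d = 1.15, t_e = 1.20,
                     v_a = 2, v_b = -1, v_c = 0.5, v_d = -0.25, v_e = 0.1,
                     valid = TRUE)
  fp <- do.call(rbind, replicate(6, beat, simplify = FALSE))
  f <- sdppg_features(fp)
  expect_length(f, 22)
  expect_equal(f[["ratio_b_a"]], -0.5)
  expect_equal(f[["agi"]], (-1 - 0.5 + 0.25 - 0.1) / 2)
  expect_equal(f[["slope_ab"]], (-1 - 2) / 0.05)
  expect_equal(f[["t_ae"]], 0.2)
  expect_equal(f[["a"]], 2)
  # identical beats: medians equal the per-beat values (already implied);
  # too few valid beats errors
  fp$valid[1:3] <- FALSE
  expect_error(sdppg_features(fp), "5 valid beats")
})

test_that("extract_features: arity, order, determinism, failure naming", {
  tr <- synth_subject("ex", rr_randomness = 0.3, noise_amp = 0.03,
                      mod_depth = 0.3, drift_amp = 0.5, seed = 17)
  rec <- generate_recording(tr)
  sig <- preprocess_recording(rec)
  pk <- detect_peaks(sig)
  f1 <- extract_features(sig, pk)
  expect_length(f1, 38)
  expect_identical(names(f1), ppg_feature_names())
  expect_true(f1[["tpr"]] >= 0 && f1[["tpr"]] <= 1)
  expect_gte(f1[["pnn20"]], f1[["pnn50"]])
  # identical recording -> identical vector
  f2 <- extract_features(preprocess_recording(generate_recording(tr)),
                         detect_peaks(preprocess_recording(generate_recording(tr))))
  expect_identical(f1, f2)
  # too few beats errors with the rr family named
  few <- ppg_peaks(c(100L, 130L, 160L), sig)
  expect_error(extract_features(sig, few), "rr family")
})
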