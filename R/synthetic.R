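#' Parametric single-beat PPG pulse template
#'
#' A smooth two-lobe pulse on the unit cycle: a primary systolic lobe
#' shaped as an asymmetric gamma-style bump (steep upstroke, slower
#' decline, like a real volume pulse) and a smaller, later Gaussian
#' dicrotic lobe. The stiffness parameter (0 = young/compliant,
#' 1 = old/stiff artery) widens the systolic lobe and enlarges and delays
#' the dicrotic lobe, which lowers the curvature of the upstroke and
#' therefore shrinks the SDPPG a-wave monotonically - the planted negative
#' a-age effect. The asymmetry keeps the a-wave the highest SDPPG maximum
#' of every cycle. The template is normalized to peak amplitude 1.
#'
#' @param stiffness numeric in [0, 1].
#' @return function mapping cycle fraction u in [0, 1) to pulse amplitude.
#' @export
beat_template <- function(stiffness) {
  if (!is.numeric(stiffness) || length(stiffness) != 1L ||
      is.na(stiffness) || stiffness < 0 || stiffness > 1)
    stop("stiffness must be a scalar in [0, 1]")
  m1 <- 0.22
  kappa <- 16 - 11 * stiffness          # effective width m1/sqrt(kappa)
  a2 <- 0.30 + 0.25 * stiffness
  m2 <- 0.55 + 0.08 * stiffness
  s2 <- 0.10
  raw <- function(u) {
    up <- pmax(u, 0) / m1
    up^kappa * exp(kappa * (1 - up)) + a2 * exp(-(u - m2)^2 / (2 * s2^2))
  }
  dense <- seq(0, 1, length.out = 2001L)
  peak <- max(raw(dense))
  u_peak <- dense[which.max(raw(dense))]
  f <- function(u) raw(u) / peak
  attr(f, "u_peak") <- u_peak
  attr(f, "stiffness") <- stiffness
  f
}

# the template is laid out on a fixed reference cycle of 0.8 s: systole has
# a roughly constant duration in real beats, so morphology (and hence the
# SDPPG waves) must not stretch with the instantaneous RR
.rr_ref <- 0.8

#' Ground truth for one synthetic subject
#'
#' Builds the stated world of a subject: beat times over ~92 s from a base
#' heart rate plus a 0.25 Hz respiratory sinus arrhythmia component
#' (fractional amplitude `rsa_depth`) and white beat-to-beat noise scaled by
#' `rr_randomness` (which therefore drives the turning point ratio of RR),
#' plus the morphology and noise parameters consumed by
#' [generate_recording].
#'
#' @param subject_id character id.
#' @param age years.
#' @param sex "male" or "female".
#' @param weight,height,smoking covariates.
#' @param stiffness morphology parameter in [0, 1].
#' @param rr_randomness white RR-noise scale in [0, 1].
#' @param heart_rate beats/minute (default 72).
#' @param rsa_depth fractional RSA amplitude (default 0.05).
#' @param noise_amp additive white-noise SD relative to pulse amplitude 1
#'   (default 0).
#' @param mod_depth respiratory amplitude-modulation depth (default 0).
#' @param drift_amp baseline drift amplitude (default 0).
#' @param duration_s record length, seconds (default 90).
#' @param seed integer seed used for every random draw of this subject.
#' @return list of class `ppg_truth`, including `beat_times` (cycle start
#'   times), `true_peak_times` (systolic peak times within the record) and
#'   `true_rr` (ms).
#' @export
synth_subject <- function(subject_id, age = 40, sex = "male", weight = 75,
                          height = 175, smoking = "no", stiffness = 0.3,
                          rr_randomness = 0.3, heart_rate = 72,
                          rsa_depth = 0.05, noise_amp = 0, mod_depth = 0,
                          drift_amp = 0, duration_s = 90, seed = 1L) {
  set.seed(as.integer(seed))
  base <- 60 / heart_rate
  # beat cycle start times covering [-1.5, duration + 1.5]
  times <- -1.5
  repeat {
    t_last <- times[length(times)]
    if (t_last > duration_s + 1.5) break
    rr <- base * (1 + rsa_depth * sin(2 * pi * 0.25 * t_last) +
                    0.15 * rr_randomness * rnorm(1))
    rr <- max(rr, 0.45)
    times <- c(times, t_last + rr)
  }
  tpl <- beat_template(stiffness)
  u_peak <- attr(tpl, "u_peak")
  peak_times <- times[-length(times)] + u_peak * .rr_ref
  in_rec <- peak_times >= 0 & peak_times <= duration_s
  structure(list(subject_id = as.character(subject_id), age = age, sex = sex,
                 weight = weight, height = height, smoking = smoking,
                 stiffness = stiffness, rr_randomness = rr_randomness,
                 heart_rate = heart_rate, rsa_depth = rsa_depth,
                 noise_amp = noise_amp, mod_depth = mod_depth,
                 drift_amp = drift_amp, duration_s = duration_s,
                 seed = as.integer(seed), beat_times = times,
                 true_peak_times = peak_times[in_rec],
                 true_rr = diff(peak_times[in_rec]) * 1000),
            class = "ppg_truth")
}

#' Synthesize one raw recording from a subject's ground truth
#'
#' Concatenates the subject's beat template along the true beat grid,
#' applies 0.25 Hz respiratory amplitude modulation, adds baseline drift
#' (slow sinusoid plus a seeded random walk) and additive white noise, and
#' samples everything on jittered ~30 Hz timestamps over ~90 s. Green, blue
#' and accelerometer channels are filled with seeded noise. Deterministic
#' given the truth (same seed, same recording).
#'
#' @param truth a `ppg_truth` from [synth_subject].
#' @return a [raw_recording] whose `meta` carries the subject covariates.
#' @export
generate_recording <- function(truth) {
  stopifnot(inherits(truth, "ppg_truth"))
  set.seed(truth$seed + 1000000L)
  dt_nom <- 1 / 30
  n_guess <- ceiling(truth$duration_s / dt_nom) + 60L
  # camera frame intervals are regular to a few percent; +-5% jitter
  dts <- dt_nom * (1 + runif(n_guess, -0.05, 0.05))
  t <- cumsum(dts)
  t <- t[t <= truth$duration_s]
  t <- t - t[1L]
  n <- length(t)
  tpl <- beat_template(truth$stiffness)
  bt <- truth$beat_times
  k <- findInterval(t, bt)
  k[k < 1L] <- 1L
  k[k >= length(bt)] <- length(bt) - 1L
  u <- (t - bt[k]) / .rr_ref     # fixed reference cycle: see .rr_ref
  pulse <- tpl(u)
  pulse <- pulse * (1 + truth$mod_depth * sin(2 * pi * 0.25 * t))
  drift <- truth$drift_amp * sin(2 * pi * 0.04 * t + runif(1, 0, 2 * pi)) +
    cumsum(rnorm(n, 0, truth$drift_amp * 0.02))
  noise <- rnorm(n, 0, truth$noise_amp)
  red <- 100 + 20 * (pulse + drift + noise)
  raw_recording(subject_id = truth$subject_id, time = t, red = red,
                green = rnorm(n, 80, 2), blue = rnorm(n, 60, 2),
                acc_x = rnorm(n, 0, 0.05), acc_y = rnorm(n, 0, 0.05),
                acc_z = rnorm(n, 1, 0.05),
                meta = list(sex = truth$sex, age = truth$age,
                            weight = truth$weight, height = truth$height,
                            smoking = truth$smoking))
}

#' Effect configuration presets for synthetic cohorts
#'
#' `strong` plants the full age effects (stiffness and RR randomness both
#' increase with age, so the SDPPG `a` feature falls and `tpr` rises with
#' age); `null` removes them (physiology independent of age).
#'
#' @param preset `"strong"` or `"null"`, or `NULL` to pass the parts
#'   explicitly.
#' @param stiffness_slope,randomness_slope multipliers on the age links.
#' @param covariate_slope multiplier on the covariate-age links (weight up,
#'   height down, smoking probability up with age); 0 makes the covariates
#'   uninformative of age.
#' @param female_offset years added to the effective physiological age of
#'   females (negative = females age more slowly).
#' @param noise_amp,mod_depth,drift_amp recording noise parameters.
#' @return named list of class `ppg_effects`.
#' @export
effect_config <- function(preset = NULL, stiffness_slope = 1,
                          randomness_slope = 1, covariate_slope = 1,
                          female_offset = 0, noise_amp = 0.03,
                          mod_depth = 0.3, drift_amp = 0.5) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("strong", "null"))
    if (preset == "null") {
      stiffness_slope <- 0
      randomness_slope <- 0
      covariate_slope <- 0
      female_offset <- 0
    }
  }
  structure(list(stiffness_slope = stiffness_slope,
                 randomness_slope = randomness_slope,
                 covariate_slope = covariate_slope,
                 female_offset = female_offset, noise_amp = noise_amp,
                 mod_depth = mod_depth, drift_amp = drift_amp),
            class = "ppg_effects")
}

.clip01 <- function(x) pmin(1, pmax(0, x))

#' Generate a synthetic cohort with known ground truth
#'
#' Ages are uniform over 18-79. The effective physiological age (true age
#' plus the configured female offset) drives stiffness and RR randomness
#' linearly with Gaussian scatter; covariates are mildly informative of age
#' (weight rises, height falls, smoking probability rises with age), as in
#' an adult population sample.
#'
#' @param n number of subjects (>= 2).
#' @param effects a [effect_config] (default strong).
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param out_dir optional directory: recordings are written in the
#'   per-subject CSV dialect plus a `truth.csv` table.
#' @return list `(truths, recordings, truth_table)`; `recordings` is a list
#'   of [raw_recording].
#' @export
generate_cohort <- function(n, effects = effect_config("strong"), seed = 1L,
                            out_dir = NULL) {
  if (n < 2L) stop("need n >= 2 subjects")
  set.seed(as.integer(seed))
  age <- round(runif(n, 18, 79))
  sex <- ifelse(runif(n) < 0.5, "male", "female")
  age_eff <- age + effects$female_offset * (sex == "female")
  frac <- (age_eff - 18) / 61
  stiffness <- .clip01(0.15 + 0.65 * effects$stiffness_slope * frac +
                         rnorm(n, 0, 0.06))
  rr_rand <- .clip01(0.15 + 0.75 * effects$randomness_slope * frac +
                       rnorm(n, 0, 0.08))
  cs <- effects$covariate_slope
  # anthropometry is deliberately sex-neutral: any covariate correlated
  # with sex would act as a sex proxy in the least-squares trend model and
  # silently re-absorb a planted sex offset (see the methods vignette)
  weight <- round(74 + cs * 0.10 * (age - 48) + rnorm(n, 0, 10), 1)
  weight <- pmax(weight, 40)
  height <- round(171 - cs * 0.06 * (age - 48) + rnorm(n, 0, 7), 1)
  smoking <- ifelse(runif(n) < plogis(-0.85 + cs * 0.025 * (age - 48)), "yes", "no")
  hr <- runif(n, 62, 82)
  subj_seed <- sample.int(1000000L, n)
  truths <- vector("list", n)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    truths[[i]] <- synth_subject(
      subject_id = sprintf("synth%04d", i), age = age[i], sex = sex[i],
      weight = weight[i], height = height[i], smoking = smoking[i],
      stiffness = stiffness[i], rr_randomness = rr_rand[i],
      heart_rate = hr[i], noise_amp = effects$noise_amp,
      mod_depth = effects$mod_depth, drift_amp = effects$drift_amp,
      seed = subj_seed[i])
    recs[[i]] <- generate_recording(truths[[i]])
  }
  truth_table <- data.frame(
    subject_id = vapply(truths, `[[`, character(1), "subject_id"),
    age = age, sex = sex, weight = weight, height = height,
    smoking = smoking, stiffness = stiffness, rr_randomness = rr_rand,
    heart_rate = hr, seed = subj_seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (r in recs) write_recording(r, file.path(out_dir, paste0(r$subject_id, ".csv")))
    write.csv(truth_table, file.path(out_dir, "truth.csv"), row.names = FALSE)
  }
  list(truths = truths, recordings = recs, truth_table = truth_table)
}

#' Feature table for an in-memory synthetic cohort
#'
#' Runs the full pipeline ([process_recording]) on each generated
#' recording and assembles the same feature table as [assemble_cohort],
#' without touching the file system.
#'
#' @param cohort result of [generate_cohort].
#' @param q_threshold quality threshold (default 0.01).
#' @return list `(cohort, exclusions)` as in [assemble_cohort].
#' @export
cohort_features <- function(cohort, q_threshold = 0.01) {
  rows <- list()
  excl <- list()
  for (rec in cohort$recordings) {
    res <- process_recording(rec, q_threshold)
    if (is.null(res$features)) {
      excl[[length(excl) + 1L]] <- data.frame(subject_id = rec$subject_id,
                                              reason = res$failure)
      next
    }
    rows[[length(rows) + 1L]] <- cohort_row(rec$subject_id, res$features, rec$meta)
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(subject_id = character(0), reason = character(0))
  if (length(rows) == 0L) stop("empty cohort: no subject survived the pipeline")
  list(cohort = do.call(rbind, rows), exclusions = exclusions)
}
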