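---
title: "From raw smartphone PPG to a vascular-aging classifier: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw smartphone PPG to a vascular-aging classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ppgage)
```

## The problem

Photoplethysmography with a phone camera measures blood-volume changes in
the fingertip: each heartbeat produces a pulse whose shape carries
information about the arterial tree. As arteries stiffen with age the
pulse's systolic upstroke softens and its dicrotic (reflected) wave moves
and grows. `ppgage` turns a ~90 s, ~30 Hz camera recording into (i) a
38-dimensional feature vector, (ii) a relevance ranking of those features
for age, and (iii) a classification of healthy vascular aging (HVA),
defined by dichotomizing chronological age: 18–38 years = HVA (class 1),
60–79 = non-HVA (class 0), 39–59 excluded from classification but retained
for the continuous-age sex-stratified analysis.

Crowd-sourced camera recordings are noisy — uninstructed pressure,
motion, ambient light — which drives three design pillars: amplitude
demodulation, a conservative voted peak detector, and a quality gate that
discards bad records *after* feature extraction (so the threshold can be
revisited without recomputation).

## Preprocessing model

Let $x(t)$ be the red-channel trace resampled (linear interpolation) onto
the uniform grid $t_0 + k/\mathrm{sf}$, $\mathrm{sf} = (n-1)/(t_n-t_1)$.

* **Detrending.** $s = x - \mathrm{CMA}_w(x)$ with $w = \mathrm{round(sf)}$
  samples (≈ 1 s), forced odd so the window is centered. The CMA passes
  baseline drift and blocks the pulse band, so subtraction is a crude but
  robust high-pass filter. Edge policy: the window truncates to the
  available samples — no data is fabricated beyond the record, at the cost
  of biased estimates within one window of each end; assertions about
  amplitude therefore exclude those edges ("interior").
* **Demodulation.** The analytic signal $s + i\mathcal{H}(s)$ (FFT
  construction on the full record) gives the instantaneous amplitude
  $|s + i\mathcal{H}(s)|$, which is smoothed with the same 1 s CMA and
  divided out. A relative floor of $10^{-3}\max(\text{envelope})$ guards
  flat stretches; floored samples are reported via an attribute. One
  consequence worth knowing: the CMA gain at pulse frequencies is not
  negligible (at 1.25 Hz and sf = 30 the 31-sample window has Dirichlet
  gain ≈ −0.196, so a detrended unit tone has amplitude ≈ 1.196); the
  demodulation stage is what restores unit scale.

## Peak detection and quality

The detector votes across six CMA window widths
$(0.5, 1, 1.5, 2, 2.5, 3)\cdot \mathrm{sf}$: per width, each maximal run of
samples *strictly above* the aligned CMA contributes its argmax (earliest
index on ties) as a partial peak; only points labelled by **all six**
widths survive (no alignment slack — all widths share one grid). The
400 ms rule then repeatedly drops the smaller of the first pair of
candidates closer than 400 ms, rescanning from the left until stable;
height ties keep the earlier peak. Small windows reject broad bumps, large
windows reject dicrotic shoulders, and the intersection is what makes the
detector conservative. A brute-force re-implementation (naive loops) is
kept in the test suite and the two must agree exactly on every tested
signal. Known edge artifact: a record that ends mid-upstroke can vote its
final rising sample a "peak"; the quality gate, not the detector, is the
defence.

Quality: $Q = \mathrm{Var}(\text{peak heights}) \cdot
(N_\text{extrema} - N_\text{detected} + 2)/N_\text{points}$, with
$N_\text{detected}$ = peaks + matched valleys (the signal minimum between
each consecutive peak pair) and local extrema counted strictly (plateaus
collapse to one extremum at their first index). Variance is the sample
variance (n−1); the variance factor captures bad demodulation, the count
factor captures noise wiggles; the +2 keeps the count factor positive when
terminal peaks lack a valley on one side. Records with $Q \ge 0.01$
(default) are excluded, with fewer than two peaks $Q = +\infty$.

## The 38 features

Three families, fixed order (`ppg_feature_names()`): 9 RR statistics,
7 successive-difference statistics, 22 SDPPG quantities. Conventions that
matter:

* pNN20/pNN50 use **absolute** differences and strict ">", returned as
  proportions in [0, 1] (so pNN20 ≥ pNN50 always).
* Skewness/kurtosis are moment-based; kurtosis is excess kurtosis; both
  return 0 on zero-variance input instead of NaN.
* The SDPPG is computed on a lightly smoothed signal (CMA of
  odd(ceiling(0.05·sf)) samples ≈ 50 ms — below the a–b spacing, so the
  waves survive; `ceiling` because 0.05·sf sits exactly on the rounding
  boundary at 30 Hz and `round` made the window flip between 1 and 3
  samples with the third decimal of the estimated sf, which bimodally
  shifted the a-wave amplitude by ~20% between recordings) and scaled by
  $\mathrm{sf}^2$.
* Fiducials: beat cycle $k$ spans valley-before-peak-$k$ to
  valley-before-peak-$k{+}1$. Zero crossings of the fourth derivative
  (sign changes, placed at the left sample) bound segments that can hold
  at most one SDPPG extremum; per segment the extremum is taken by the
  segment's concavity and must be a strict local extremum of the sampled
  SDPPG — but it *may* sit on the segment boundary, because at 30 Hz the
  true extremum frequently quantizes onto the crossing sample (requiring
  interior position invalidated most beats). `a` is the highest maximum
  candidate and must dominate the entire cycle's SDPPG, b–e follow as the
  next alternating minima/maxima; beats missing any wave are flagged
  invalid, never dropped silently. Per-record SDPPG features are medians
  over valid beats, requiring ≥ 5.

## Ranking and classification

Features and covariates are standardized by train-set median and IQR
(binary covariates with the same rule; a zero-IQR column is flagged and
zeroed with a warning — this is visible behaviour, not a bug). The ridge
ranking repeats 100 times: subsample 2/3 of the training rows, fit linear
ridge (continuous age) and logistic ridge (HVA label) with the penalty
tuned by 10-fold CV over 30 log-spaced values in $[10^{-3}, 10^3]$, rank
variables by decreasing |coefficient|, average the ranks per model, sum
the two averages. Rank-then-average (not average-coefficients-then-rank)
is implemented. Caveat established empirically with the simulator: when
several features are children of one latent factor, ridge spreads
coefficient mass among them and *which sibling* ranks first is not
identifiable — rankings should be read at the family level.

Classification uses an RBF-kernel least-squares SVM (no SVM library ships
in the target runtime; the LS-SVM dual is a single linear solve and keeps
the margin-based kernel-classifier contract), with C ∈ {0.1, 1, 10, 100}
and kernel width scale-based ×{0.1, 1, 10}, tuned by 3-fold CV on AUC.
ROC curves step through unique score values (ties move diagonally), AUC is
the trapezoidal area — equal to the concordant-pair probability, which the
tests verify by enumeration — and the reported sensitivity/specificity sit
at the Youden-optimal point of the test ROC (the operating-point rule is
otherwise unconstrained).

### The sex-stratified trend and why sex is not in it

The trend model is `age ~ a + tpr + weight + height + smoking`, fitted on
the training set (all ages), predicted on the test set, smoothed per sex by
LOWESS (span 2/3) on a common grid restricted to each sex's inner 5–95%
age quantiles (LOWESS is unreliable where a sex has little support). The
sex dummy is deliberately excluded: least squares with the stratification
variable among the regressors forces each sex's mean residual to zero, so
the two curves would coincide by construction and the analysis could never
show the sex difference it exists to show. For the same reason the
simulator draws weight and height identically for both sexes — any
covariate correlated with sex acts as a linear sex proxy and silently
re-absorbs a planted sex offset.

## The synthetic cohort: what it emulates, what it does not

A subject is a beat grid (base rate 62–82 bpm; 0.25 Hz respiratory sinus
arrhythmia of fractional depth 0.05; white beat-to-beat noise scaled by an
age-linked `rr_randomness`), a pulse template, and a measurement layer
(respiratory amplitude modulation depth 0.3 at 0.25 Hz, slow-sinusoid +
random-walk drift, additive white noise sd 0.03 of pulse amplitude,
timestamps at 30 Hz with ±5% frame jitter — camera frame timing is regular
to a few percent).

The template is an asymmetric gamma-shaped systolic lobe plus a Gaussian
dicrotic lobe on a **fixed 0.8 s reference cycle**. Two choices here are
load-bearing. The asymmetry (steep upstroke, slow decline) keeps the
SDPPG a-wave the highest maximum of every cycle; a symmetric systolic bump
makes the post-peak rebound (c) exceed a, which no real pulse does. The
fixed reference cycle reflects that systole has roughly constant duration
regardless of RR; stretching the template with the instantaneous RR turns
the a-wave into a heart-rate readout instead of a stiffness readout.
Stiffness ∈ [0, 1] widens the systolic lobe (gamma shape 16 → 5) and
enlarges/delays the dicrotic lobe, so the a-wave falls monotonically with
stiffness; stiffness and `rr_randomness` rise linearly with effective age
(true age plus an optional female offset) under `effect_config("strong")`
and are age-independent under `"null"`.

What a green test does **not** establish: the simulator has no motion
artifacts, no baseline saturation, no skin-tone or contact-pressure
effects, sex-neutral anthropometry, exactly linear age–physiology links,
and a single template family — so passing recovery tests validates the
pipeline's mechanics, not clinical performance. The study's real-data
headline numbers (AUC ≈ 0.95 etc.) are computed on a non-public cohort and
are deliberately not targets of this package's tests.

## Numerical choices and degenerate inputs

* Windows are forced odd (+1) so "centered" means centered; edges truncate.
* Duplicate timestamps keep the first occurrence; non-monotone time errors.
* All-zero signals error at demodulation (degenerate envelope); envelope
  division is floored at $10^{-3}$ of the envelope maximum.
* FDPPG zero crossings at the left sample of each sign change: grid-level
  precision is the attainable resolution at 30 Hz.
* Fewer than 2 peaks → Q = +∞; fewer than 4 RR intervals or 5 valid beats →
  the feature family errors with its name, and cohort assembly logs the
  subject with that reason.
* The stratified split allocates test slots by largest remainder across age
  deciles, so a 3612-subject cohort at fraction 0.25 yields exactly
  2709/903.
* Ridge repetitions that fail to converge are retried once with reshuffled
  folds (warning), then error.

## Known limitations

30 Hz undersamples the SDPPG waves — 20–30% of beats per record typically
fail the five-wave assignment and are flagged; the median over valid beats
is the defence. The quality gate passes slow drift that the detrender
removes anyway, and the peak detector's end-of-record artifact (final
rising sample voted a peak) is inherited from the voting scheme. The LS-SVM
solves a dense n×n system: fine for cohorts of thousands, not for hundreds
of thousands.
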