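Package: ppgage
Title: Vascular-Aging Analysis of Smartphone Photoplethysmography Signals
Version: 0.1.0
Authors@R:
    person("PPG", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for fingertip photoplethysmography (PPG)
    recordings acquired with a smartphone camera: detrending by centered
    moving average, Hilbert-envelope demodulation, six-window systolic peak
    detection, signal-quality scoring, extraction of 38 waveform features
    (inter-beat-interval statistics, successive-difference statistics and
    second-derivative-PPG a-e wave quantities), repeated ridge-regression
    feature ranking, and classification of healthy vascular aging, together
    with a synthetic PPG cohort simulator with known ground truth for
    offline validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
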