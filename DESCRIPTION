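Package: mibci
Title: Motor-Imagery EEG Simulation, Preprocessing and PSO-SVM Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for two-class (left/right) motor-imagery
    brain-computer interface analysis: trial-paradigm scheduling, a synthetic
    multichannel EEG generator with scene-gain-scaled contralateral
    event-related desynchronization (ERD), a four-stage cleaning chain
    (moving-average baseline removal, adaptive LMS 50 Hz cancellation, ICA
    blink removal, zero-phase 8-32 Hz Butterworth band-pass), fused
    mean-square / Welch band-power / common-spatial-pattern features, a
    particle-swarm-optimized RBF support vector machine, three-fold offline
    assessment, online recognition-rate tables, and topographic fourth-order
    energy brain activation maps with breadth/depth metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    ica,
    RcppTOML,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
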