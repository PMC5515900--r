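Package: crossday
Title: Cross-Day EEG Emotion Classification with Robust Principal
    Component Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mitigating day-to-day variability in EEG-based
    emotion classification. Implements spectral band-power and MESH
    asymmetry feature extraction from epoched multi-channel EEG, per-trial
    robust principal component analysis (principal component pursuit via
    the inexact augmented Lagrange multiplier method) separating low-rank
    background activity from sparse emotion-related oscillations, F-score
    feature ranking with F-distribution p-values, Gaussian naive Bayes
    classification with balanced repeated cross-validation and an
    add-feature-in scheme, and the add-day-in (ADI) cross-day validation
    protocol. Includes a synthetic multi-day data generator emulating the
    low-rank-plus-sparse structure the method assumes, so the full
    pipeline is testable without access to recorded EEG.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
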