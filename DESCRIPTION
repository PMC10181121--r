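Package: eegchsel
Title: EEG Channel Selection for Biometric Identification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Ranks EEG channels by their contribution to subject
    identification and finds the smallest channel subset that preserves
    identification accuracy. Per-epoch beta-band features (multitaper
    band power, hemispheric asymmetry indices, phase-locking values) are
    ordered by relevance with a PCA or Wilcoxon signed-rank backend,
    converted into weighted channel scores, and evaluated by incremental
    subset classification with a cross-validated RBF-kernel support
    vector machine. Includes an EDF reader/writer, a beta-band
    preprocessing pipeline, and a multi-subject EEG simulator with
    planted subject-specific spectral and phase-coupling structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
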