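Package: sdaudit
Title: Performance Auditing of Neonatal EEG Seizure Detection Algorithms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in-depth performance-analysis toolkit for automated neonatal
    EEG seizure detection algorithms (SDAs). Matches detector event lists
    against expert gold-standard seizure annotations across sensitivity
    thresholds and computes event-based (seizure detection rate, false
    detections per hour) and epoch-based (sensitivity, specificity) metrics;
    houses a ten-feature seizure assessment schema (amplitude, rhythmicity,
    morphology, duration, frequency variability, spatial spread); models
    which seizure features predict automated detection with random-intercept
    logistic regression (univariate screen, collinearity filter, backward
    stepwise selection, AUC comparison); categorizes false detections into an
    artefact taxonomy with per-patient concentration and threshold drop-off
    analyses; and bundles a synthetic-data generator with a minimal reference
    detector so the whole pipeline can be exercised end-to-end against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    pROC,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
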