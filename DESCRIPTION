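Package: fearsense
Title: Fear Recognition from Wearable Physiological Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A binary fear-recognition pipeline for tri-channel physiological
    recordings (electrocardiogram, galvanic skin response and skin
    temperature). Provides fixed-window segmentation with recovery-slot
    trimming, linear-phase FIR denoising with automatic gain control, a
    48-feature extractor combining time-domain, spectral and non-linear
    descriptors (heart-rate variability, tonic/phasic electrodermal
    decomposition with trough-to-peak SCR detection, recurrence
    quantification analysis, multiscale sample entropy, detrended
    fluctuation analysis and correlation dimension), fear labeling from
    pleasure-arousal-dominance self-reports, and subject-dependent and
    leave-one-subject-out evaluation of SVM, KNN and boosted-tree
    classifiers tuned by sequential model-based optimization. A synthetic
    session generator with ground-truth physiology makes the whole pipeline
    testable without access to restricted datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    lhs,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
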