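Package: mieeg
Title: Channel Selection and Regularized Common Spatial Patterns for
    Motor-Imagery EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-class motor-imagery electroencephalography (EEG)
    classification. Implements a hybrid statistical channel-selection method
    (per-channel Welch t-tests with Bonferroni correction plus an
    inter-channel correlation criterion), shrinkage-regularized common
    spatial pattern (CSP) feature extraction with Ledoit-Wolf covariance
    shrinkage and an L2-regularized linear refinement, and small
    feed-forward and recurrent neural-network classifiers evaluated under
    stratified 5-fold cross-validation. Includes readers and writers for
    BCI Competition style MAT containers and EDF files, marker-aligned
    epoching with Butterworth band-pass preprocessing, a synthetic generator
    of event-related desynchronization (ERD) with ground-truth
    discriminative channels, and a configuration-driven pipeline with
    machine-readable run reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    tools,
    utils,
    graphics,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
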