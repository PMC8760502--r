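Package: srafnet
Title: Timing-Aware Labeling and Residual Convolutional Modeling of
    Atrial Fibrillation Risk from Sinus-Rhythm ECGs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how label timing affects deep-learning
    detection of atrial fibrillation (AF) from 12-lead sinus-rhythm
    electrocardiograms.  Provides a seeded synthetic ECG-cohort generator
    (patient timelines plus Gaussian-bump PQRST waveforms with a tunable
    AF signature), cohort inclusion/exclusion and AF/SR labeling rules
    with three index-ECG timing modes, balanced 5-second sample
    construction with sliding-window oversampling and a patient-level
    7:1:2 split, a temporal-plus-lead-axis residual convolutional
    classifier implemented on base R linear algebra, and an evaluation
    battery with DeLong AUC intervals, exact Clopper-Pearson intervals,
    and bootstrap F1 intervals.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
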