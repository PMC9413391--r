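Package: afsync
Title: Atrioventricular-Synchronization Features and Dense Neural Networks
    for Atrial Fibrillation Detection in Multi-Lead ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rule-based delineation of R-waves, QRS onsets and P-/f-peaks in
    multi-lead ECG; extraction of six atrioventricular-synchronization
    statistics (RR-interval, PQ-interval and PQ-amplitude mean and standard
    deviation) per lead set; a grid-searched shrinking dense neural network
    classifier for atrial fibrillation and flutter versus all other rhythms,
    trained with class-weighted binary cross-entropy and an operating point
    selected at maximal validation balanced accuracy; and Shapley-value
    feature-importance reports. Includes a 12-lead synthetic ECG generator
    with ground-truth fiducials, a minimal WFDB format-16 reader and writer,
    and patient-wise stratified dataset partitioning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    optparse
Config/testthat/edition: 3
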