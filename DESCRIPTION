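Package: doceeg
Title: EEG Complexity, Connectivity and Outcome Analysis for Anesthesia in
    Disorders of Consciousness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for comparing anesthetic agents in patients
    with disorders of consciousness from multichannel EEG and clinical
    follow-up: permutation entropy of the ongoing EEG, phase-locking-value
    gated weighted phase lag index (wPLI) connectivity in canonical
    frequency bands, cluster-based permutation testing of time-frequency
    power maps, normality-routed group comparisons with effect sizes and
    Benjamini-Hochberg false discovery rate control, and confounder-adjusted
    logistic and linear outcome models with likelihood-ratio comparison of
    EEG-augmented fits. Includes a seeded synthetic-data module that
    generates multichannel EEG with controllable band power, lagged
    cross-channel coupling and zero-lag volume-conduction mixing, plus
    clinical cohorts with a group effect on three-month improvement, so the
    whole pipeline is testable without patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
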