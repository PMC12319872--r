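Package: thoughtprobe
Title: Electrophysiological Signatures and Decoding of Ongoing-Thought Dimensions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulation-backed pipeline for studying multi-dimensional
    experience sampling (MDES) with EEG. Generates synthetic task and rest
    EEG cohorts with planted thought-dimension effects, preprocesses and
    epochs continuous recordings, extracts periodic (aperiodic-subtracted)
    spectral power on an electrode-by-frequency grid, applies Likert
    dichotomization and inclusion rules, runs dependent-samples
    cluster-based permutation tests and linear mixed-model controls,
    computes task-rest spectral similarity, and decodes thought dimensions
    with a shallow 1D convolutional network evaluated by within-participant
    cross-validation and leave-one-participant-out transfer learning with
    SMOTE balancing and permutation significance testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
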