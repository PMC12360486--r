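Package: innerspeech
Title: Offline Analysis of Inner and Attempted Speech in Motor Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing the neural representation of inner
    (imagined) versus attempted speech in intracortical recordings.
    Provides a synthetic trial-structured session generator with per-word
    tuning shared across behaviors, behavior-specific modulation scaling,
    a behavior-offset ("motor-intent") vector, block-wise drift and
    count/power observation noise; Gaussian-kernel smoothing, block-wise
    centering and window averaging; nested cross-validated Gaussian naive
    Bayes word decoding with exact Clopper-Pearson intervals; bias-reduced
    cross-validated distance and correlation estimators with normalized
    distance tables and PCA word rings; motor-intent dimension fitting and
    removal with word-versus-behavior accuracy decomposition; position-wise
    binary LDA sequence decoding with bootstrap inference; aggregate word
    error rate with bootstrap and permutation chance; dynamic-time-warped
    logit correlation; and OLS control analyses (articulatory-length
    tuning, counting-slope inference with a stitched-trial null).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    e1071
Config/testthat/edition: 3
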