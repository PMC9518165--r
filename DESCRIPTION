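Package: laughcep
Title: Cepstral Analysis of Laughter for Parkinson's Disease Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Signal-processing and classification toolkit for laughter-based
    screening of hypokinetic dysarthria, the speech-motor disorder of
    Parkinson's disease. Implements the cepstral front-end used in speech
    recognition (pre-emphasis, Hanning framing, power spectra, triangular
    Mel/Human-Factor/Bark filter banks, discrete cosine cepstra with delta
    and delta-delta dynamics), pools per-frame coefficients into per-laugh
    moment vectors, augments small cohorts by multivariate-normal sampling
    of per-group feature moments, and evaluates random-forest, k-nearest
    neighbour and nu-SVC classifiers under subject-wise cross-validation
    with accuracy rate, Matthews correlation and ROC/AUC metrics. Includes
    a parametric laugh-bout synthesizer with controllable jitter, shimmer,
    breath noise and articulation smearing for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    ranger,
    jsonlite,
    yaml,
    withr,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    pROC,
    optparse
Config/testthat/edition: 3
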