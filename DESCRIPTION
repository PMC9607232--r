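Package: mfcnn
Title: Matched-Filter Interpretation of 1D Convolutional Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building, training and interpreting shallow
    one-dimensional convolutional classifiers as banks of matched filters.
    Provides a synthetic template-signal simulator with controlled additive
    white Gaussian noise and time shifts, a classical matched-filter
    classifier used as a learning-free oracle, univariate and multivariate
    (depthwise) matched-filter CNN architectures with a self-contained
    training engine, evaluation metrics, kernel-versus-template
    interpretation analyses, and adapters for wearable-sensor human
    activity recognition datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0), SummarizedExperiment
Imports: methods, stats, utils, graphics, grDevices, S4Vectors, jsonlite,
    yaml, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
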