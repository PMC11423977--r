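Package: cgmbench
Title: Benchmarking Deep Sequence Models for Blood Glucose Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible benchmark of five deep forecasting architectures
    (feed-forward, convolutional, temporal convolutional, LSTM and
    self-attention networks) for short-horizon blood glucose prediction from
    continuous glucose monitoring (CGM) traces. Provides a multi-cohort
    synthetic CGM simulator with realistic bimodal glucose densities and
    sensor dropout, grid alignment and gap-aware linear imputation, sliding
    window construction, seeded training with Adam under an early-stopping
    protocol, analytical metrics (RMSE, MAD, coefficient of determination,
    FIT, MADP), Clarke Error Grid clinical scoring, cross-cohort
    generalization matrices with two-sample Kolmogorov-Smirnov residual
    comparison, and demographic-slice bias analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
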