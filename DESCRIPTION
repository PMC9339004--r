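Package: evacc
Title: Evidence-Accumulation Task Modeling and Convolutional Poisson
    GLMs for Parietal Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analyzing neural evidence accumulation in a
    sequential probabilistic-reasoning task. Models the task's
    stimulus/reward structure (base-10 logistic reward rule over summed
    shape weights), estimates behavioral subjective weights and
    epoch-level leverage with base-10 logistic regression, and fits
    convolutional Poisson generalized linear models with per-lag
    temporal kernels to 10-ms binned spike trains. Inference on fitted
    kernels includes trial-shuffle null distributions, longest-run
    significance with encoding latency and sign, coefficients of
    partial determination, population kernel tests, selectivity
    classification, and reduced-major-axis (model II) regression. A
    synthetic-data generator produces behavioral choices and
    inhomogeneous Poisson spike trains with planted kernels so that
    every stage of the pipeline can be validated by parameter recovery
    and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
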