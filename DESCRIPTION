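Package: megp
Title: Single- and Multi-Environment Bayesian Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genomic prediction toolkit for plant breeding trials. Provides
    marker quality control and kernel construction (genomic relationship and
    Gaussian kernels with kernel averaging), best linear unbiased estimates of
    line means from randomized complete block designs, Gibbs samplers for
    whole-genome regression (GBLUP, reproducing kernel Hilbert spaces
    regression, BayesB, BayesC) with scaled inverse chi-square priors, a
    marker-by-environment interaction ridge-regression model with heterogeneous
    residual variances, bivariate GBLUP for genomic correlations with inverse
    Wishart priors, multi-environment cross-validation designs (CV0, CV1, CV2)
    with the corrected resampled t-test, and a synthetic-data generator with
    known genetic architecture for end-to-end validation of the pipeline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    lme4,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
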