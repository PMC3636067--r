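Package: updrsdyn
Title: Short-Term Dynamics of Self-Reported Parkinson's Disease Symptoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying short-term (days-to-weeks) dynamics in
    longitudinal self-reported Unified Parkinson's Disease Rating Scale
    (UPDRS) Parts I+II series. Provides per-patient piecewise-linear convex
    trend estimation on irregular time grids (total-variation penalty on the
    discrete slope) with cross-validated selection of the regularization
    constant, pooling of detrended residuals, gamma generalized linear
    modeling of mean absolute fluctuation versus time since diagnosis,
    bootstrap skewness testing, two-sample Kolmogorov-Smirnov distributional
    validation with quantile-quantile pairing, clinically-important-difference
    scaling for the Parts I+II subscale, and a calibrated synthetic cohort
    generator emulating high-frequency online self-report data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
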