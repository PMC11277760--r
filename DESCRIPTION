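Package: ivcalib
Title: Instrumental-Variable Calibration Estimators for Finite-Population Totals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design-based and model-based estimation of finite-population
    totals when some auxiliary variables are endogenous, i.e. correlated with
    the errors of the working linear model. Implements classical calibration
    weighting (chi-square closed form and Newton iteration for general
    distance functions, equivalent to the generalized regression estimator),
    the Horvitz-Thompson baseline with its SRSWOR design variance, and
    instrumental-variable calibration estimators in model-assisted (IVC) and
    model-based (MBIVC) flavours for exactly identified systems, together
    with plug-in variance and mean-square-error formulas. Includes a
    synthetic-population generator with controllable endogeneity and
    instrument strength, and a Monte-Carlo harness tabulating bias and MSE
    per estimator, sample size and endogeneity setting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
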