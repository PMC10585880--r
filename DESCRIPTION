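Package: baselinemort
Title: Baseline Mortality Prediction Methods and Their Simulation-Based
    Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting baseline (expected) weekly all-cause
    mortality for excess-mortality calculations, and for comparing
    prediction methods on synthetic data.  Implements a negative-binomial
    weekly death-count simulator with a long-term trend, sinusoidal
    seasonality and randomly occurring Cauchy-shaped winter and summer
    peaks; four baseline predictors (seasonal average, linear trend, a
    WHO-style penalized thin-plate spline model and an
    Acosta-Irizarry-style quasi-Poisson spline model); and a Monte-Carlo
    evaluation harness reporting mean squared error, mean absolute
    percentage error and bias of predicted yearly death totals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    splines,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
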