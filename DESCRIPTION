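Package: rddalert
Title: Regression Discontinuity Evaluation of Threshold-Triggered
    Clinical Deterioration Alerts
Version: 0.1.0
Authors@R:
    person("rddalert", "maintainers", email = "rddalert@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating threshold-triggered clinical
    early-warning alerts with a sharp regression discontinuity design.
    Provides a synthetic cohort generator with a known causal effect at
    the alert threshold, local polynomial regression discontinuity
    estimation with triangular kernel weights and MSE-optimal
    (Calonico-Cattaneo-Titiunik style) bandwidth selection, the McCrary
    density manipulation test, a falsification suite (covariate balance,
    placebo cohorts, assignment discontinuity), bandwidth sensitivity
    sweeps, and an end-to-end analysis pipeline with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
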