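Package: glucopop
Title: Stochastic Virtual Patient Populations for Type 1 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds stochastic virtual populations of people with type 1
    diabetes from continuous glucose monitor (CGM) streams, self-reported
    meal/insulin/activity logs and heart-rate data. A compartmental
    glucose-dynamics simulator (insulin, meal, physical-activity and
    heart-rate driven chains feeding a central glucose ODE) is embedded in a
    four-level hierarchical Bayesian model (cohort, patient, 24h sample,
    event) and fitted by stochastic variational inference with a low-rank
    multivariate normal guide. Includes a 24h-window extraction and quality
    filtering pipeline, a synthetic-cohort generator with known ground
    truth, prior- and posterior-predictive simulation with intraday and
    interday variability resampling, and glycemic evaluation metrics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
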