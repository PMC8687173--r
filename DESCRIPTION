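Package: glucofilt
Title: Sigma-Point State Estimation for a Glucose-Insulin Meal Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a twelve-state physiological model of glucose-insulin
    homoeostasis with oral meal intake (gastric emptying, intestinal
    absorption, endogenous glucose production, insulin secretion and
    hepatic extraction) for healthy and type-2-diabetic virtual patients,
    and estimates all unmeasured states from noisy plasma-glucose
    measurements alone with two Gaussian sigma-point Bayesian filters:
    the unscented Kalman filter and the cubature quadrature Kalman filter
    (third-degree spherical cubature combined with generalized
    Gauss-Laguerre radial quadrature). Includes a Monte-Carlo RMSE
    benchmark of the two filters, reproducible truth/measurement
    synthesis, YAML configuration, CSV export and diagnostic plots.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
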