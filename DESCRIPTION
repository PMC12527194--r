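Package: pulsedose
Title: Personalized Arterial Pulse Wave Propagation Modelling and
    Vasopressor Dose-Change Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pulsatile blood flow in a 71-segment 0-1D arterial
    network with time-varying elastance inflow and Windkessel outflow
    boundaries, personalizes the model to multi-site oscillometric volume
    waveforms and cuff pressures by Levenberg-Marquardt estimation of five
    patient-specific parameters, provides Sobol sensitivity and
    identifiability-based parameter selection, and predicts the direction
    of norepinephrine dose changes within 24 hours using a binomial mixed
    model with stepwise AIC feature selection and leave-one-out
    cross-validation. Includes a fully synthetic cohort generator with
    oscillometric-style distortion and planted dose dynamics so that every
    stage of the pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    minpack.lm,
    lme4,
    lhs,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
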