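Package: cardioresp
Title: Closed-Loop Cardiorespiratory Simulation of Aerobic Exercise in
    Health and Heart Failure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lumped-parameter closed-loop simulator of the human
    cardiorespiratory response to graded cycling exercise. Couples a
    time-varying elastance heart and a twelve-compartment systemic and
    pulmonary circulation to respiratory mechanics, alveolar and tissue
    gas exchange, an arterial baroreflex with exercise resetting,
    local metabolic vasodilation with functional sympatholysis, and a
    chemoreflex ventilation controller. Ships complete parameter sets for
    a healthy subject and a chronic heart-failure patient, reproduces
    steady-state hemodynamics and ventilation at rest and at graded
    workloads, and provides open-loop stimulus-response sweeps of the
    reflex sub-models.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
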