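Package: svpulse
Title: Stroke Volume Estimation from Non-Invasive Pulse-Wave Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates 1-D pulse-wave propagation in a reduced systemic
    arterial tree with three-element Windkessel terminal boundaries,
    generates age- and gender-stratified synthetic haemodynamic cohorts,
    trains a gradient-boosting regressor that predicts left-ventricular
    stroke volume from nine non-invasive inputs (age, gender, weight,
    height, brachial SBP/DBP/PP/MAP and carotid-femoral pulse wave
    velocity), and evaluates predictions against thermodilution-style
    reference tables with Bland-Altman agreement statistics and
    hemodynamic-coherence filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    yaml,
    jsonlite,
    xgboost,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
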