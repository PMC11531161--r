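Package: fontansim
Title: Lumped-Parameter Hemodynamics of the Failing Fontan Circulation
    with Systemic Ventricular Assist
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Closed-loop zero-dimensional (lumped-parameter) simulation of the
    single-ventricle Fontan circulation supported by a continuous-flow systemic
    ventricular assist device. Cardiac chambers follow a time-varying elastance
    model with an exponential end-diastolic and linear end-systolic
    pressure-volume relation; the systemic and pulmonary beds are modified
    three-element Windkessel networks; the rotary pump follows a quadratic
    pressure-head/flow characteristic. The package provides scenario factories
    for four failing-Fontan pathophysiologies (systolic dysfunction, diastolic
    dysfunction, atrioventricular valve regurgitation, elevated pulmonary
    vascular resistance), pump-speed ramp and stressed-blood-volume titration
    protocols, a pulmonary-vascular-resistance sweep, tidy beat-averaged
    hemodynamic summaries, and ggplot2 figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
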