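Package: atriahemo
Title: Closed-Loop Lumped-Parameter Modelling of Left Atrial Hemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A zero-dimensional (lumped-parameter) closed-loop model of the
    systemic and pulmonary circulations centred on left atrial (LA)
    reservoir, conduit and pump function. Chambers follow a time-varying
    elastance law with a linear end-systolic and an exponential
    end-diastolic pressure-volume relation; vascular beds are
    resistance-capacitance (windkessel) compartments and valves are ideal
    diodes. The package simulates sinus rhythm, atrial flutter,
    irregular-cycle atrial fibrillation and left atrial appendage occlusion
    (LAAO) scenarios, and provides the hemodynamic analysis layer used to
    quantify them: a/c/v wave detection on LA pressure, mitral E/A peaks,
    stroke volume and cardiac output, figure-eight pressure-volume loop
    decomposition by self-intersection, LA appendage ejection fraction, and
    derivative-free calibration of free circuit parameters against target
    hemodynamic features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
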