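Package: rocumep
Title: Neuromuscular Blockade Depth and the Reliability of Intraoperative
    Motor-Evoked Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A pharmacometric pipeline quantifying how the depth of
    rocuronium-induced neuromuscular blockade (observed as the T1/Tc
    train-of-four twitch ratio) governs intraoperative motor-evoked-potential
    (MEP) amplitudes and their within-subject variability. Provides
    compartmental effect-site simulation of rocuronium, inhibitory sigmoid
    Emax models linking effect-site concentration to T1/Tc and to mean MEP
    amplitude in four muscles, closed-form analysis and shape classification
    of the amplitude-T1/Tc relationship, a bi-exponential model of the
    coefficient of variation of repeated MEP amplitudes, nonlinear
    mixed-effects estimation of the population dose-response parameters,
    virtual-cohort simulation of the monitoring design, and derivation of
    critical T1/Tc thresholds for reliable MEP interpretation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    jsonlite,
    Matrix,
    nlme,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
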