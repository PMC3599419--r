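Package: dfrcest
Title: Model-Based Estimation of PEEP-Induced Dynamic Functional Residual
    Capacity from Ventilator Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating dynamic functional residual capacity
    (dFRC) -- the end-expiratory lung volume gained through positive
    end-expiratory pressure (PEEP) -- from routine mechanical-ventilation
    pressure-flow waveforms. Implements four estimators: a stress-strain
    multiple-breath method using volume responsiveness across PEEP steps
    with a per-PEEP population constant, a stress-strain single-breath
    method using tidal-volume-normalised inspiratory compliance, a
    single-compartment method based on fitted respiratory elastance, and a
    combined method that switches between them as PEEP steps accrue.
    Includes waveform reading and breath segmentation, integral-based
    identification of the single-compartment equation of motion,
    population-constant calibration with leave-one-out evaluation, a
    synthetic ventilated-patient simulator with known ground-truth dFRC,
    and measured-versus-estimated agreement reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
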