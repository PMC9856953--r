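Package: mhtsim
Title: Controller-in-the-Loop Simulation of Temperature-Feedback Magnetic Hyperthermia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates temperature-feedback controlled magnetic hyperthermia
    therapy (MHT) at desk scale. Provides a discrete PID control law with
    anti-windup and output saturation, a safety supervisor with per-sensor
    temperature thresholds and automatic resume, linear voltage-to-field
    actuator maps with nanoparticle, copper-wire and eddy-current heat source
    models, reduced-order thermal plants (lumped first-order-plus-dead-time
    and a 1-D radial Pennes bioheat solver), a fiber-optic multi-sensor probe
    model, CEM43 thermal dosimetry, and controller performance metrics (rise
    time, settling time, overshoot, steady-state error). Ships scenario
    presets for gel-phantom verification, ex vivo liver and in vivo canine
    brain control sessions, pulse-response system identification and
    model-based PID retuning, and CSV/YAML session and scenario formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
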