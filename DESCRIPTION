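Package: kneeload
Title: EMG-Informed Estimation of Tibiofemoral Contact Force Under Added Limb Mass
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Desk-scale pipeline for estimating compressive tibiofemoral (knee)
    contact force during walking from joint kinematics, ground reaction forces
    and surface electromyography, and for quantifying how mass added to the
    thigh, shank or foot changes the early- and late-stance contact-force
    peaks. Implements a planar sagittal musculoskeletal model with twelve
    Hill-type muscle-tendon units, a two-stage (calibration/execution)
    EMG-informed muscle redundancy optimization with reserve actuators, a
    torque-driven intersegmental joint-reaction decomposition, a synthetic
    gait-trial generator with known ground truth, and the statistical layer
    (through-origin multiple regression, random-intercept mixed models, and
    noncentral-F power analysis) used to relate added segment mass to percent
    change in peak knee contact force.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
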