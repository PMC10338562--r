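Package: submax
Title: Maximal Oxygen Uptake Prediction from Submaximal Cycle-Ergometer Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a first-order differential response model of heart rate and
    oxygen uptake to submaximal incremental cycle-ergometer recordings,
    extrapolates heart rate under a continued ramp workload to an estimated
    maximum, and reads off the predicted maximal oxygen uptake (VO2max) at
    that moment. Includes resting-parameter estimators for maximal heart
    rate (Whyte) and VO2max (Jurca), a retrospective truncation-point study
    that characterises prediction error against the fraction of maximal
    heart rate at which a test is stopped, and a synthetic-cohort generator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    deSolve,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
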