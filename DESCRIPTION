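Package: sacchoice
Title: Simulation and Analysis of Saccadic-Choice Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for two-alternative saccadic-choice experiments in
    visual psychophysics. Generates fully balanced experimental designs
    and synthetic 1000 Hz gaze traces with planted ground truth,
    equalizes stimulus luminance and contrast by affine matching,
    detects saccade onsets with a velocity-threshold plus
    derivative-sign algorithm and anticipation/fixation-break
    rejection filters, estimates the minimum reliably accurate saccadic
    reaction time by bin-wise Monte Carlo chi-square tests with a
    consecutive-bins rule, and runs a mixed-effects inference workflow
    (logit models on accuracy, linear models on log reaction times)
    with random-effect selection by likelihood-ratio tests, Type III
    analysis of deviance, and parametric-bootstrap confidence
    intervals.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    car,
    stats,
    utils,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
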