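Package: pursuitTTC
Title: Smooth-Pursuit and Time-to-Contact Analysis Pipeline
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing, simulating, and analysing step-ramp
    (Rashbass) smooth-pursuit experiments with a time-to-contact button-press
    task. Includes the factorial session generator (visual condition by object
    velocity), a ground-truth-annotated synthetic eye-trace and response
    generator at 1 kHz, eye-movement preprocessing (central-difference
    differentiation, 80-tap 30-Hz FIR low-pass filtering, velocity and
    acceleration saccade detection, desaccading, blink handling, trial-level
    quality control), pursuit metrics (latency, initial acceleration,
    steady-state velocity, saccade rate), time-to-contact error metrics
    (constant, absolute, variable error, reaction time, previous-trial
    tables), within-subject statistics (two-way repeated-measures ANOVA with
    partial eta squared, Bonferroni pairwise follow-ups, within-subjects
    correlation), and a deterministic end-to-end pipeline driver with
    CSV and JSON interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
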