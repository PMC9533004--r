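Package: whipkin
Title: Kinematic Analysis of Whip-Manipulation Motion Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing three-dimensional motion-capture recordings of
    a targeted whip-manipulation task. Provides marker-trajectory input/output
    with gap accounting, zero-lag Kaiser-window FIR low-pass filtering and
    differentiation, segmentation of continuous recordings into discrete and
    rhythmic trials with temporal landmarks (throw onset, peak hand speed,
    minimum whip-target distance), per-trial performance and whip-shape metrics
    (minimum-distance error, hit detection, whip extension and azimuth, hand
    azimuth, peak speeds, inter-trial rhythmicity), time-normalised ensemble
    speed profiles, and linear/generalised mixed-effects models of performance
    with participant-level random effects. A scripted kinematic scene generator
    produces synthetic whip-throw recordings with known ground truth so every
    stage of the pipeline can be validated in closed loop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lme4,
    lmerTest,
    pracma,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
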