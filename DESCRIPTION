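Package: fallsentry
Title: User-Adaptable Fall Detection from Depth-Sensor Skeleton Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects unintentional human falls from depth-sensor skeleton
    streams (20 named joints plus a floor-clipping plane, 30 frames/s).
    Computes per-frame kinematics (height above the floor plane, movement
    direction, irregular-movement distance, speed, acceleration), gait-derived
    fall-risk factors (step symmetry, trunk sway, arm spread) with a binary
    fall-risk level, and runs a two-stage five-process detection algorithm
    that adapts its monitoring path to the user's risk level before
    confirming or rejecting fall candidates.  Includes a seeded synthetic
    skeleton-motion simulator with labelled activities, an accelerometer
    height-reconstruction adapter for benchmark replay, and a
    confusion-matrix evaluation harness (accuracy, sensitivity, specificity,
    precision).  A command-line interface exposes simulation, detection,
    risk scoring and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
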