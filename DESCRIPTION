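Package: wearlab
Title: Wearable Gait Analysis from IMU and Multi-Channel EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully wearable gait-analysis pipeline: gait-event detection
    from foot-worn inertial sensors, whole-body ground-reaction-force
    estimation from segment accelerations with a smooth-transition split
    between feet, a heel-to-toe centre-of-pressure progression model,
    sagittal joint angles from sensor orientations, planar ankle inverse
    dynamics, and an EMG-driven Hill-type musculoskeletal model of the ankle
    with person-specific calibration. Includes a self-consistent synthetic
    gait generator (segment kinematics, inertial signals, 64-channel EMG,
    and ground-truth loads and torques) providing a known-answer test
    surface for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
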