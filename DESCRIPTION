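Package: gaitfuse
Title: Cooperative Kalman Filtering and Calibration for Wearable Inertial
    Sensors in Gait Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates absolute sagittal-plane segment angles (trunk, thigh,
    shank, foot) from body-worn inertial measurement units and exoskeleton
    potentiometers. Implements three discrete error-state Kalman filters: a
    per-segment local filter, a cooperative matricial filter over the stacked
    states of all sensors, and a Markov jump filter that fuses the currently
    most reliable accelerometer with potentiometer joint angles. Includes two
    inertial sensor calibration pipelines (a simplified six-position/90-degree
    protocol and a complex turntable protocol with rate-dependent scale
    correction), a synthetic gait and sensor-rig simulator used for end-to-end
    verification, performance metrics, and a factorial evaluation harness
    comparing filters across calibration qualities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
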