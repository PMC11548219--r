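Package: shoegait
Title: Shoe-Mounted Force-Sensor and IMU Gait Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Processing pipeline for instrumented-shoe gait data combining
    four plantar triaxial force sensors with a toe-mounted inertial
    measurement unit (IMU). Provides accelerometer gain/bias calibration,
    quaternion-based Euler-angle tracking, transformation of localized
    ground reaction forces (GRF) into the ground frame, stance-phase
    detection and 101-point time normalization, zero-velocity-update (ZUPT)
    double integration with piecewise-linear drift cancellation for stride
    length and toe clearance, minimum-toe-clearance extraction, and
    group-comparison statistics (coefficients of variation, unpaired t-tests,
    Cohen's d, Bland-Altman agreement). A synthetic gait simulator generates
    ground-truth sessions with young- and older-adult variability profiles
    so every stage is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    pracma,
    withr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
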