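Package: gaitipm
Title: Stride-by-Stride Spatial Gait Parameters from Shank-Mounted IMUs
Version: 0.1.0
Authors@R:
    person("Gait", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs stride-by-stride spatial gait parameters (stride
    length, stride velocity, shank vertical displacement) from a single
    six-axis inertial measurement unit mounted on each shank. Orientation is
    estimated by gravity alignment at every mid-stance and forward quaternion
    integration of the gyroscope; the double-integration drift is removed
    with a per-stride linear error model anchored by an inverted-pendulum
    update velocity at mid-stance (with a zero-velocity-update baseline for
    comparison). Includes gait-event detection from the sagittal angular
    velocity, a physically consistent walking-shank simulator with full
    ground truth, Bland-Altman style agreement statistics, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
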