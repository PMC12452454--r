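Package: imukam
Title: Knee Adduction Moment Estimation from Two Inertial Measurement Units
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the external knee adduction moment (KAM) during walking
    from two body-worn inertial measurement units: a lower-back (L3) sensor
    providing a vertical ground reaction force surrogate and a lower lateral
    shank sensor providing the frontal-plane shank tilt angle. The KAM is
    approximated as the product of the vertical ground reaction force and a
    frontal-plane lever arm (shank length times the sine of the shank tilt).
    Includes zero-phase Butterworth filtering, quaternion tilt estimation from
    quiet-standing calibration plus gyroscope integration, single-limb-support
    detection from contralateral force-plate data, 101-point gait-cycle time
    normalization, waveform similarity scoring via the coefficient of multiple
    correlation (CMC), and a synthetic gait simulator that provides ground
    truth for validating the full estimation chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
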