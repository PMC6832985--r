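Package: lumbargait
Title: Clinical Gait, Balance and Timed Up and Go Features from a Single Lumbar IMU
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts a complete set of 184 clinical movement features from one
    lower-back inertial measurement unit (triaxial accelerometer and gyroscope)
    worn during three standardized clinical tests: the 10 m Walk Test, the five
    static standing conditions of the Berg Balance Scale, and the Timed Up and
    Go.  Gait events (initial and end contacts) are detected from the vertical
    acceleration with Gaussian-derivative continuous wavelet transforms; step
    length follows an inverted-pendulum model with a shoe-size-calibrated
    correction, using empirical mode decomposition with a Hurst-exponent rule
    to remove integration drift; postural sway is summarized by spectral,
    time-domain and 95% covariance-ellipse features; Timed Up and Go phases are
    segmented from Daubechies discrete-wavelet approximations of pitch and yaw.
    Includes seed-deterministic synthetic signal generators with exact ground
    truth, and Bland-Altman, intraclass-correlation and Pearson/RMSE agreement
    statistics for validating estimates against a gold standard.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
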