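Package: magstep
Title: Step Detection and Counting from Single-Axis Magnetometer Traces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects and counts walking steps from a single-axis magnetic
    field time series recorded by a wrist-worn magnetometer. The arm swings
    like a pendulum during walking, periodically modulating the measured
    Earth-field component; steps appear as local extrema of the low-pass
    filtered signal. The package implements the full streaming pipeline --
    a three-subblock circular buffer, block-wise FIR low-pass filtering with
    historical warm-up, strict local-extrema detection, a
    complementary-extremum threshold test that rejects fake steps caused by
    ambient field fluctuations, and a motionless-phase detector that
    suppresses extrema while standing -- together with a seeded synthetic
    arm-swing trace simulator with ground-truth step times, and an
    evaluation harness scoring detected against true step counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics
Suggests:
    signal,
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
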