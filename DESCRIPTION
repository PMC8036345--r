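Package: rscmonitor
Title: Wearable Body-Temperature Monitoring with Accelerometer-Based
    Exercise Recognition and Adaptive Fever Alerts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Streaming analysis engine for wrist-worn quarantine
    monitoring. Implements first-order IIR low-pass filtering and
    reference-based bias calibration of contact thermometer streams, the
    Repetition Spikes Counter (RSC) that classifies physical exercise from
    windowed spike counts in consecutive Z-axis acceleration differences,
    an activity-adaptive fever threshold with a post-exercise hold timer,
    a dwell-time alert state machine with infrared confirmation requests,
    indoor temperature and relative-humidity range checking, and a
    sample-and-hold telemetry pipeline that fuses the three sensor
    streams. Includes seeded synthetic-signal generators for
    accelerometer, body-temperature and indoor-condition streams, CSV and
    JSON-lines readers and writers, and a command-line interface.
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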