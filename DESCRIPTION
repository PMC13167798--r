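Package: strawtrack
Title: RFID Movement Tracking and Mixed-Model Analysis for Group-Housed Pigs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning event-level RFID signal-strength logs from
    barn-mounted receivers into an hourly animal-movement metric, and for
    analysing that metric with longitudinal mixed models. Includes
    log-distance path-loss calibration of RSSI to distance, incremental
    movement aggregation with validity rules, a restricted maximum
    likelihood (REML) engine for the random-intercept model with AR(1)
    residual correlation within animal-day (least-squares means, Type-3
    F tests with containment degrees of freedom, intraclass correlation,
    BLUPs), a weighted mixed model of movement on environmental covariates
    (temperature, humidity, particulate matter) over day-by-timeline
    blocks, and a synthetic barn/sensor data generator that emulates the
    statistical structure of a deep-straw finishing pen so the whole
    pipeline is testable without proprietary farm data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme,
    lme4,
    jsonlite,
    optparse
Config/testthat/edition: 3
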