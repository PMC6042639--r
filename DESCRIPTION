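Package: puffr
Title: Detection of Cigarette Smoking from Wrist-Worn Motion Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A three-stage analysis pipeline that detects individual
    cigarette drags and smoking instances from 6-axis inertial
    measurement unit (IMU) streams recorded on the dominant wrist.
    Stage one turns raw accelerometer and gyroscope samples into
    discrete motion-feature events (hand raising to mouth, hand
    stationary at mouth, hand lowering) using gyroscope binning with a
    stationarity threshold and a decision-tree window classifier.
    Stage two assembles raise/dwell/lower triplets with bounded
    durations into single-drag detections. Stage three aggregates
    drags into smoking-instance detections using a minimum drag count
    and a bounded inter-drag interval. The package also provides a
    seeded simulator of labelled smoking, drinking, eating and
    walking gestures for training and benchmarking, and an
    event-level evaluation module (precision, recall, accuracy,
    Cohen's kappa) with a free-living mode that omits true negatives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    rlang,
    rpart,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
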