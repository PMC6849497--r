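Package: falldetect
Title: Multi-Sensor Wearable Fall Detection by Classifier Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects patient falls from wearable tri-axial accelerometer and
    gyroscope recordings, distinguishing them from activities of daily living
    (staying still, lying down, sitting up, standing up, bending). Per-axis
    signal power forms a six-dimensional feature space classified in parallel
    by a k-nearest-neighbour classifier (with cross-validated choice of k) and
    a Gaussian naive Bayes classifier; a threshold-gated frame-difference
    visual classifier contributes a third binary vote, and a three-input
    majority gate fuses the votes into the fall/non-fall decision. Includes a
    seeded simulator of labelled motion recordings and frame sequences,
    delimited-text readers and writers, sensitivity/specificity/accuracy
    evaluation, and a command-line pipeline (simulate, train, classify,
    evaluate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
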