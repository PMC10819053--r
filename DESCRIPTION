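Package: mcae
Title: Multi-Channel Asymmetric Auto-Encoders for Wearable-Sensor Activity Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-task representation learning for human activity recognition from
    multi-channel wearable time series (IMU accelerometer/gyroscope/magnetometer
    channels). Implements a per-channel 1-D convolutional asymmetric auto-encoder
    whose shared latent space drives both signal reconstruction (Huber loss) and
    activity classification (cross-entropy), together with the supervised and
    classical shared auto-encoder baselines, the preprocessing pipeline (median +
    zero-phase Butterworth filtering, sliding-window segmentation with majority
    labels, train-only standardization), subject-disjoint evaluation with
    classification reports and latent-space PCA diagnostics, an activation-function
    reconstruction harness, and a seeded synthetic multi-subject IMU generator so
    the whole pipeline is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
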