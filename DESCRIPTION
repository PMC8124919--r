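Package: kicksense
Title: IMU-Based Shot and Pass Detection for Football
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and classification of football shots and passes against a
    null class from foot-worn inertial measurement unit (IMU) streams. Provides
    a labelled synthetic-session generator emulating gait background, ball-contact
    impact signatures and clap-based synchronization patterns; three-clap sync
    detection, sampling-rate estimation and resampling to a uniform 200 Hz axis;
    Butterworth high-pass / signal-magnitude-vector peak detection for candidate
    window selection; a kick-phase feature SVM baseline; compact 1D-CNN, LSTM and
    convolutional-LSTM sequence classifiers with a native SGD training loop; and
    an imbalanced multiclass evaluation harness (weighted F1, per-class
    sensitivity, fine-grained column-normalized confusion matrices) over
    segmented and moving-window scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
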