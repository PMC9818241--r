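Package: adaptanchor
Title: Adaptive IoU-Threshold Anchor Matching for Small-Object Detection
    in Hand Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Anchor-based detection of small, partially clustered objects in
    radiograph-like images, with a focal-loss feature-pyramid detector whose
    anchor assignment uses intersection-over-union (IoU) thresholds that ramp
    up over the first training epochs instead of staying fixed. Built around
    scoring of joint erosions on bilateral hand radiographs (Sharp/van der
    Heijde scores 0-5 over 32 joint sites): includes DICOM-style window/level
    normalization, box-consistent data augmentation, a seeded synthetic
    bilateral-hand generator for end-to-end testing without clinical data,
    training with oversampling and plateau learning-rate scheduling, and the
    bespoke evaluation metrics (per-class precision mAP, correct-detection
    accuracy, mean IoU, score confusion matrices, Kendall tau agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
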