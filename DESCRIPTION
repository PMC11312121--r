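Package: steatoscope
Title: Colour and Texture Assessment of Hepatic Steatosis from Calibrated Liver Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grades donor-liver steatosis from RGB photographs taken with a
    neutral grey reference card in frame. Provides grey-card colour
    calibration (gamma linearisation, white balance, exposure
    normalisation), CIELAB conversion, liver-mask handling with a baseline
    colour-threshold segmenter, random non-overlapping patch sampling with
    specular-highlight rejection, colour-histogram and local-binary-pattern
    texture features, class-weighted patch classifiers (random forest and
    RBF support vector machine) trained under donor-level stratified nested
    cross-validation, fraction-of-patches liver-level aggregation, and
    evaluation utilities (bootstrap confidence intervals, ROC/AUC, exact
    McNemar test, feature importance). A seeded synthetic-case generator
    renders liver scenes with known ground-truth steatosis so the full
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    EBImage,
    ranger,
    e1071,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
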