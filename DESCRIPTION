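Package: boxfusion
Title: Weighted Boxes Fusion Ensembles for Medical Object Detection
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for combining and evaluating axis-aligned bounding-box
    predictions from multiple object detectors, aimed at anatomical and
    pathological structure detection in brain MRI slices. Implements
    non-maximum suppression and weighted boxes fusion (confidence-weighted
    averaging of overlapping boxes), four ensemble strategies over a grid of
    models and cross-validation folds (all folds of a model, above-mean folds,
    all models per fold, best model per fold), and a detection evaluation
    suite: intersection over union, greedy prediction/ground-truth matching,
    per-class average precision and mAP, and FROC analysis (true positive rate
    against false positives per image) with its area summary. A seeded
    synthetic scene and multi-detector simulator emulating per-slice object
    statistics of brain MRI, plus COCO-style JSON readers/writers and a
    command-line interface, make the whole pipeline runnable end to end
    without any imaging data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    pracma,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
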