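Package: tilsagree
Title: Inter-Observer Agreement Measures for TILs Scoring on Histopathological Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Interpretable inter-observer agreement measures for tumor-infiltrating
    lymphocyte (TILs) assessment on histopathology images. Implements pixel-wise
    Fleiss' kappa and a Boundary-Weighted Fleiss' kappa (BWFK) for multi-observer
    stromal segmentation masks, a ground-truth-free Distance-Based Cell Agreement
    Algorithm (DBCAA) for point-marked lymphocyte detections, stromal TILs score
    derivation with physical calibration, dataset-level concordance statistics
    (intraclass correlation, Bland-Altman limits of agreement with the mean,
    cross-measure correlation tests), mask/point perturbation sensitivity analyses,
    and a synthetic multi-observer annotation generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
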