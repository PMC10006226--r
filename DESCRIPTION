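Package: chromtex
Title: Nuclear Chromatin Texture Analysis with GLCM and Wavelet Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies chromatin texture of cell nuclei in histology
    micrographs from masked regions of interest. Computes six gray-level
    co-occurrence matrix (GLCM) features (angular second moment, inverse
    difference moment, contrast, correlation, sum average, sum variance)
    and first-level 2D Haar wavelet detail-subband energies (EnLH, EnHL,
    EnHH) per nucleus, compares feature distributions between injured and
    control groups with the Mann-Whitney U test, and trains logistic
    regression, support vector machine and random forest classifiers with
    ROC/AUC evaluation. Includes a seeded two-class synthetic nucleus
    generator for end-to-end validation of the pipeline, plus tools to
    score a human rater's binary calls against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    png,
    tiff,
    yaml,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
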