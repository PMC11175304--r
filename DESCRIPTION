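Package: etongue
Title: Voltammetric Electronic-Tongue Preprocessing and Cluster-to-Classes Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for voltammetric electronic-tongue data aimed at
    discriminating food samples (tomato puree cultivars) from cyclic-voltammetry
    scans acquired with an array of chemically modified screen-printed electrodes.
    Provides a seeded synthetic cyclic-voltammetry generator that emulates the
    acquisition protocol (per-electrode replicate structure, scan-to-scan
    amplitude decay, forward/backward hysteresis, analyte-driven oxidation
    peaks), the scan-wise min-max normalization, cross-sensor range
    equalization, window-average subsampling and concatenation preprocessing
    stage, projection (LDA or PCA) plus KMeans cluster-to-classes classifiers
    with nearest-centroid test assignment, off-the-shelf random-forest and
    support-vector comparators, repeated random-split evaluation with macro
    precision/recall/F1, sensor-block ablation, majority-vote measurement-wise
    classification, and a one-way ANOVA check on monosaccharide content.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
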