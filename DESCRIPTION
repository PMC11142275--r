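Package: cytosar
Title: Multiplexed Phospho-Flow Screening Analysis for Structure-Activity Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for fluorescent-cell-barcoded phospho-flow
    chemical screens: barcode deconvolution by per-dye Gaussian mixtures,
    arcsinh scaling and rule-based quality-control gating, KNN-enrichment
    comparison of treated versus vehicle cells with a degree-of-difference
    statistic, Marker Enrichment Modeling against a statistical-null
    reference, fold-change hit selection with vehicle-derived thresholds,
    cell-type specificity scoring, and four-parameter log-logistic
    dose-response fitting. Includes a ground-truth-labeled synthetic plate
    generator so every stage is testable without instrument data, and
    minimal FCS 3.1 read/write plus a CSV event dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rtsne,
    RANN,
    minpack.lm,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    uwot,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
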