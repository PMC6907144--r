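Package: eigencell
Title: Supervised Cell-Type Classification by Informative Principal
    Component Projection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains calibrated one-versus-all support vector machine
    classifiers for single-cell RNA-seq cell types in a truncated SVD
    eigenspace of the log-CPM expression matrix. Class-informative
    principal components are selected by two-tailed Wilcoxon rank-sum
    tests with Benjamini-Hochberg correction; independent cells are
    projected through the stored rotation and assigned by a
    maximum-probability rule with a rejection option, so cell types
    absent from the training data are labelled "Unassigned" rather than
    forced into a known class. Includes quality-control and gene
    filters, Platt probability calibration, SMOTE class balancing,
    hierarchical (lineage-tree) classification, rejection-aware
    evaluation metrics with bootstrap confidence intervals, read
    downsampling, a negative-binomial simulator for class-structured
    count matrices, and a portable on-disk model bundle format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    kernlab,
    digest,
    jsonlite,
    methods,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
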