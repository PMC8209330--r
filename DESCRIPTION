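Package: texroi
Title: Texture Analysis and Classification of Paired Grayscale Image Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes a 25-feature texture panel (histogram moments,
    gray-level run-length features, gray-level co-occurrence features) on
    paired lesion/control grayscale image regions, compares the groups with
    Shapiro-Wilk and exact paired Wilcoxon signed-rank tests, screens
    ambiguous samples with a t-SNE embedding plus a per-sample t statistic,
    ranks features by random-forest mean-decrease-Gini importance, and
    trains and evaluates random-forest, support-vector-machine and
    back-propagation neural-network classifiers with AUC, error rate,
    sensitivity and specificity over repeated stratified splits. Includes a
    synthetic paired-patch generator (smoothed Gaussian noise fields) for
    building reproducible test cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    randomForest,
    e1071,
    nnet,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    cluster,
    optparse
Config/testthat/edition: 3
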