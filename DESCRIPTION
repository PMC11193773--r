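Package: angiopep
Title: Sequence-Based Classification of Anti-Angiogenic Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating sequence-based classifiers of
    anti-angiogenic peptides. Peptide sequences are transformed into a
    comprehensive numeric feature vector (58 descriptor types, 4335 values,
    spanning compositional, sequence-order and physicochemical-scale
    descriptors), robust-scaled by median and interquartile range, ranked with
    a shadow-feature (Boruta-style) random-forest procedure, and reduced by a
    heuristic top-N subset search driven by cross-validated Matthews
    correlation. Six classifier families (SVM, LDA, random forest, extremely
    randomized trees, gradient-boosted trees, elastic-net logistic regression)
    can be tuned with a tree-structured Parzen estimator and benchmarked with
    stratified cross-validation and independent tests, including post-hoc
    analyses of prediction probability and residue-property strata. A
    synthetic-data module generates labeled peptide sets and feature matrices
    with known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    digest,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    MASS,
    purrr,
    ranger,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
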