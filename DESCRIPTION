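Package: targetprops
Title: Protein Properties and Cross-Validated Classification of Drug Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds family-aware drug-target / non-target protein datasets,
    computes sequence- and annotation-derived physicochemical descriptors
    (amino-acid composition, hydrophobic moment, isoelectric point,
    Wilkinson-Harrison solubility, PEST regions, PTM proportions, solvent
    accessibility, expression level and tissue-specificity tau), compares the
    two groups feature-by-feature (chi-square / Wilcoxon rank-sum, exact
    enrichment), and classifies targetability with leakage-aware
    cross-validation (linear squared-hinge SVM and random forest, per-fold
    feature selection and min-max scaling fit on training folds only). A
    synthetic-data generator with planted class effects makes every stage
    testable without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
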