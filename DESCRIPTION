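Package: opncb
Title: Optimized Permutation Nested ComBat Harmonization for Radiomic
    Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@opncb.org",
           role = c("aut", "cre"))
Description: Empirical-Bayes ComBat harmonization of categorical
    acquisition-protocol effects in radiomic feature tables, applied
    sequentially over several acquisition parameters in the permutation
    that leaves the most features acquisition-independent (Optimized
    Permutation Nested ComBat). Supports collective harmonization,
    covariate harmonization preserving a biological subgrouping, and
    per-subgroup separate harmonization, with strict fit-on-train /
    apply-to-unseen semantics and the rare-instance exclusion rules
    needed for heterogeneous clinical cohorts. Includes a Kruskal-Wallis
    acquisition-independence gate, a LASSO to linear-SVM malignancy
    classifier, a repeated stratified cross-validation harness with
    DeLong ROC-AUC comparisons and Holm-Bonferroni adjustment, and a
    synthetic cohort generator with known ground-truth biology and
    per-subgroup batch effects for benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    e1071,
    jsonlite,
    yaml
Suggests:
    sva,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
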