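Package: cernet
Title: Competing Endogenous RNA Network Inference and Dysregulation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers miRNA-mediated mRNA-lncRNA competing endogenous RNA (ceRNA)
    pairs from miRNA-target interaction catalogs using a hypergeometric
    miRNA-sharing test, prunes them into condition-specific co-expression
    networks, and detects condition-specific dysregulation of pairs with a
    label-permutation differential-correlation test. Includes microarray probe
    re-annotation by exact sequence matching, single-sample gene-set enrichment
    (ssGSEA) scoring with lncRNA-pathway association, ROC/AUC and exhaustive
    marker-panel cross-validation with support-vector machines, descriptive
    network statistics, and a synthetic two-condition cohort generator with
    planted ceRNA structure for ground-truth evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    Biostrings,
    e1071,
    jsonlite
Suggests:
    fgsea,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
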