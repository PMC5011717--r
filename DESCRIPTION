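Package: wbdecon
Title: Deconvolution-Based Disease-Specific Classification of Whole-Blood
    Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-blood gene expression is a mixture over hematopoietic cell
    types, and many diseases share a common myeloid-up/lymphoid-down shift in
    cell composition that confounds single-disease biomarker studies. wbdecon
    deconvolutes bulk expression into a cell-component profile (marker-based
    DSA-style or signature-based non-negative least squares) and a per-sample
    residual expression profile obtained by removing the cell-frequency-
    explained component of each gene, and builds disease-specific classifiers
    on both feature spaces with a leakage-controlled independent-dataset
    evaluation schema (control-anchored Z-transformation, elastic-net branches,
    posterior-product combination). It also provides cross-dataset
    meta-analysis tools (informative-gene pooling, fold-change similarity
    clustering, permutation-FDR detection of commonly regulated genes,
    cell-component change statistics) and a synthetic whole-blood cohort
    simulator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    limma,
    pracma,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
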