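Package: camrad
Title: Tumour Subregion Decomposition and Radiogenomic Survival Analysis
    for Dynamic Contrast-Enhanced MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised decomposition of dynamic contrast-enhanced MRI
    tumour kinetics into vascular compartments by convex analysis of
    mixtures (affinity propagation clustering of pixel time-series,
    minimum-error-margin convex-hull corner identification,
    simplex-constrained proportion estimation, and minimum description
    length model-order selection), grey-level co-occurrence-matrix
    radiomics over the whole tumour and the decomposed subregions,
    Cox/Kaplan-Meier survival stratification of imaging features with
    optimal log-rank cutoffs and Benjamini-Hochberg correction, and a
    radiogenomic map linking prognostic features to co-expression module
    eigengenes and elastic-net multigene signatures with hypergeometric
    pathway enrichment.  A synthetic-data module generates images,
    survival tables and expression matrices with known ground truth so
    every stage is testable without access to clinical cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    survival,
    glmnet,
    RNifti,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
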