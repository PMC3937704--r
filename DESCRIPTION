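Package: MorphoCog
Title: Random-Forest Mapping of Regional Brain Morphometry to Cognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A two-stage random-forest pipeline linking regional brain
    morphometry (cortical thickness and ICV-normalized striatal volumes) to
    cognitive performance in case-control cohorts such as prodromal
    Huntington disease studies. Stage one learns normative age/sex effects on
    each region from gene-negative controls with a random-forest regressor,
    residualizes both groups, and screens regions for case-group atrophy with
    one-sided Wilcoxon rank-sum tests under Benjamini-Hochberg FDR control.
    Stage two ranks the surviving regions by out-of-bag permutation
    importance aggregated over repeated forest fits (covariates included),
    and selects a parsimonious top-k model by the minimum mean out-of-bag
    MSE curve with an optional one-standard-error rule. Includes a synthetic
    cohort generator with known ground truth, covariate-adjusted group
    comparisons for cognitive outcomes, and a reproducible pipeline runner.
    The regression-forest engine (bootstrap CART with out-of-bag permutation
    importance) is implemented in C++ via Rcpp.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    Rcpp,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
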