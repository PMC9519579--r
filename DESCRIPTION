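Package: content
Title: Context-Shared and Context-Specific Genetic Prediction of Gene
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds genetic predictors of gene expression for studies in
    which the same individuals are measured across many contexts (tissues
    of a bulk RNA-seq study, cell types of a single-cell study). Observed
    expression is decomposed into a context-shared (between-individual)
    component and context-specific (within-individual) deviations;
    penalized regression on cis genotypes yields a predictor for each
    component, and the two are recombined per context into a full
    predictor. Includes the standard per-context elastic-net and joint
    group-LASSO comparators, hierarchical false discovery rate control
    over the gene/context/model hypothesis tree, a simulation framework
    with correlated intra-individual noise, and individual-level
    transcriptome-wide association (TWAS) power evaluation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    data.table,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    yaml,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
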