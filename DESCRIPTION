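Package: ethnoprs
Title: Ethnicity-Stratified Polygenic Risk Modeling for COPD-Like Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating ethnicity-specific polygenic
    risk models of a dichotomous disease outcome with a continuous
    endophenotype (an FEV1 analogue). Implements genotype/phenotype quality
    control, genomic-relationship-matrix construction, restricted maximum
    likelihood (REML) estimation of SNP heritability (single and
    chromosome-partitioned), per-SNP BLUP screening from a linear mixed
    model, partially-penalized logistic regression (lasso, ridge, elastic
    net with unpenalized clinical covariates) tuned by nested
    cross-validation on AUC, cross-population external validation, and a
    deviance-based decomposition of variable contributions (McFadden's
    pseudo R-squared). A multi-ethnic cohort simulator with a
    Balding-Nichols population-structure model, configurable heritability
    and cross-population causal-variant overlap makes the whole pipeline
    testable without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
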