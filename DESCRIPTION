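Package: multipgs
Title: Multi-Polygenic Scores for Coronary Heart Disease by Penalized
    Combination of Single-Trait Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and evaluates multi-polygenic scores (multi-PGS) for
    binary disease outcomes such as coronary heart disease. Prepares GWAS
    summary statistics (case-control effective sample sizes, variant quality
    control, fixed-effects inverse-variance meta-analysis with genomic
    control), computes per-sample polygenic scores from PGS Catalog style
    scoring files with allele harmonization, combines many scores by lasso
    logistic regression with unpenalized covariates and 10-fold
    cross-validation, collapses the fitted combination into a single
    variant-level scoring file, and evaluates models (odds ratio per SD,
    Nagelkerke R2, AUC with DeLong intervals, percentile bootstrap, decile
    prevalence, FDR-controlled association scans). A liability-threshold
    simulator generates pleiotropic multi-trait cohorts so the whole
    pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
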