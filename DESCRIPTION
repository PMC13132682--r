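Package: methylcog
Title: Blood DNA Methylation Proxy Scores for General Cognitive Ability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds and validates parsimonious blood DNA-methylation proxy
    scores for general cognitive ability (g). Provides probe- and sample-level
    quality control for Illumina-style beta-value matrices, derivation of g as
    the first unrotated principal component of a standardized
    neuropsychological battery, a penalty-factor elastic net (penalized CpGs,
    unpenalized cell/sex/batch covariates) tuned by fixed-fold cross-validation
    with the per-alpha one-standard-error rule, portable scoring of new cohorts
    from a serialized model artifact, and a validation battery: incremental
    validity, MCI discrimination with DeLong and likelihood-ratio tests,
    age-residualized comparison against an epigenetic-aging comparator,
    moderation, bootstrap mediation, partial correlations, and dual-criterion
    outlier sensitivity. A seeded synthetic-cohort generator emulating two
    array platforms with partially overlapping probe panels makes the whole
    workflow testable end to end without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
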