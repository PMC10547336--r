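Package: mrdissect
Title: Dissecting Pleiotropic Pathways in Two-Sample Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (MR) workflow for
    dissecting the causal effect of a liability exposure on a binary outcome
    into direct, mediated and horizontally pleiotropic channels. Provides
    summary-statistic ingestion and allele harmonization, greedy LD clumping,
    inverse-variance weighted estimation with multiplicative random effects,
    MR-Egger and weighted-median sensitivity analyses, radial MR outlier
    detection with per-variant Cochran's Q contributions, TRYX-style
    candidate-trait scanning with FDR filtering, LASSO pruning and
    SNP-outcome adjustment, multivariable MR for direct effects and
    qualitative mediation comparison, and a synthetic GWAS summary-statistic
    generator with known ground truth so every stage is verifiable by
    parameter recovery at desk scale.
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
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
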