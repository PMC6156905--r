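Package: famgxm
Title: Family-Based Tests of Gene-by-Methylation Interactions on
    Quantitative Treatment Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and inference toolkit for pharmacoepigenetic
    SNP-by-CpG interaction tests on a quantitative posttreatment outcome in
    family samples. Provides pedigree handling and kinship coefficient
    matrices, a family-clustered cohort simulator in which CpG methylation
    linearly suppresses a causal SNP effect on log triglycerides, and three
    estimators for the interaction test: a linear mixed model with a
    kinship-structured genetic random effect, generalized estimating
    equations with robust and Mancl-DeRouen bias-corrected covariances, and
    quadratic inference functions with an analogous leverage-based
    correction. A scan layer fits every model across simulated replicates
    under baseline-adjusted and change-score outcome settings and summarizes
    empirical power and Type I error at nominal and Bonferroni thresholds.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
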