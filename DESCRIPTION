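Package: shortscale
Title: Short-Form Scale Construction and Validation from Ordinal Questionnaire Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs short-form psychometric instruments from ordinal
    (Likert) response data with a genetic algorithm that maximises
    internal consistency under a polynomial length penalty, with expert
    "core" items locked into every candidate subset. Provides the full
    companion validation workflow: classical test theory reliability
    (Cronbach's alpha with Bonett or Feldt confidence intervals,
    alpha-if-item-deleted, corrected item-total correlations, scaled mean
    ratings), polychoric correlation matrices and maximum-likelihood
    exploratory factor analysis with a second-eigenvalue unidimensionality
    check, a polytomous Rating Scale Model estimated by marginal maximum
    likelihood that accommodates missing-by-design responses,
    normality-gated convergent validity correlations and known-groups
    comparisons, and reliability-precision sample-size planning. A seeded
    synthetic-cohort generator makes every stage testable without access
    to clinical data.
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
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    mvtnorm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
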