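Package: qgtrial
Title: Quantitative Genetic Evaluation of Open-Pollinated Progeny Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pedigree-based quantitative genetic evaluation of forest-tree
    progeny trials with explicit handling of population structure. Builds the
    numerator relationship matrix and its sparse inverse from open-pollinated
    (half-sib) pedigrees, fits univariate, bivariate and across-site animal
    models by average-information REML, and derives narrow-sense heritability,
    additive and type-B genetic correlations, quantitative-trait population
    differentiation (Qst) and estimated breeding values, each with
    Taylor-series (delta-method) standard errors. Includes k-fold
    cross-validation of predictive ability and prediction accuracy for
    comparing evaluation models that include or exclude a population-structure
    fixed effect, and a synthetic two-site half-sib trial generator with known
    variance components for end-to-end validation.
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
    methods,
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
    knitr,
    lme4,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
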