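#' Published reference estimates for two spruce progeny trials
#'
#' Variance-component, heritability and cross-validation tables reported by a
#' quantitative-genetic evaluation of growth and wood properties in two large
#' southern Swedish Norway spruce open-pollinated progeny trials (Horeda and
#' Erikstorp; 18 traits), under two evaluation models: model A (population
#' structure ignored) and model B (population fixed effect included).
#' Shipped as plain-text tables and used as worked-example input for the
#' arithmetic identities of this package (heritability ratios, model
#' contrasts, relative accuracy improvements); the underlying phenotype data
#' are not public, so these printed estimates are the only external anchor.
#'
#' Note: in the source table, one printed row (Horeda, model B, TTangW) is
#' internally inconsistent -- its printed heritability does not equal
#' `sigma2_A / (sigma2_A + sigma2_e)` for its printed variance components
#' under any rounding of the inputs; values are transcribed as printed.
#'
#' @return A tibble: per site (`Horeda`/`Erikstorp`), model (`A`/`B`) and
#'   trait, the additive variance, residual variance and narrow-sense
#'   heritability with standard errors; or, for `spruce_reference_cv()`, the
#'   5-fold cross-validation predictive ability (with SE) and prediction
#'   accuracy per site, trait and model.
#' @export
spruce_reference_estimates <- function() {
  readr::read_csv(system.file("extdata", "spruce_trial_estimates.csv",
                              package = "qgtrial", mustWork = TRUE),
                  show_col_types = FALSE)
}

#' @rdname spruce_reference_estimates
#' @export
spruce_reference_cv <- function() {
  readr::read_csv(system.file("extdata", "spruce_trial_cv.csv",
                              package = "qgtrial", mustWork = TRUE),
                  show_col_types = FALSE)
}
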