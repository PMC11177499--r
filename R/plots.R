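#' Plot variance parameters of a REML fit
#'
#' Dot-and-error-bar plot of the variance parameters (estimate +- 1 SE).
#'
#' @param object A `qg_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qg_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$estimate - .data$std.error,
      ymax = .data$estimate + .data$std.error
    )) +
    ggplot2::labs(x = NULL, y = "estimate",
                  title = "REML variance parameters (+-1 SE)") +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation correlations
#'
#' @param object A `qg_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qg_cv <- function(object, ...) {
  ggplot2::ggplot(object$per_fold,
                  ggplot2::aes(x = factor(.data$fold), y = .data$correlation)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$pa, linetype = 2) +
    ggplot2::labs(
      x = "fold", y = "EBV-phenotype correlation",
      title = sprintf("Predictive ability, %s (model-%s): PA = %.3f",
                      object$trait, object$model_variant, object$pa)
    ) +
    ggplot2::theme_minimal()
}

#' Population performance boxplots
#'
#' Phenotypic or breeding-value distributions by population for one trait,
#' the standard display for comparing population performance in a
#' provenance-style analysis.
#'
#' @param trial A [trial_data()] object.
#' @param trait Trait name.
#' @param ebv Optional EBV table from [compute_ebv()]; when supplied the
#'   breeding values are plotted instead of phenotypes.
#' @return A ggplot.
#' @export
plot_population_performance <- function(trial, trait, ebv = NULL) {
  if (is.null(ebv)) {
    df <- trial$data |>
      dplyr::filter(!is.na(.data$population), !is.na(.data[[trait]]))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$population,
                                     y = .data[[trait]])) +
      ggplot2::geom_boxplot() +
      ggplot2::labs(x = "population", y = trait,
                    title = paste("Phenotypic performance:", trait)) +
      ggplot2::theme_minimal()
  } else {
    df <- dplyr::filter(ebv, !is.na(.data$population))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$population, y = .data$ebv)) +
      ggplot2::geom_boxplot() +
      ggplot2::labs(x = "population", y = "EBV",
                    title = paste("Genetic performance (EBVs):",
                                  unique(df$trait)[1])) +
      ggplot2::theme_minimal()
  }
}

#' Qst profile across traits
#'
#' Dot plot of Qst estimates (+- 1 SE) per trait and site, the standard
#' display for ranking traits by population differentiation.
#'
#' @param qst_table Tibble as returned by row-binding [qst()] results.
#' @return A ggplot.
#' @export
plot_qst <- function(qst_table) {
  ggplot2::ggplot(qst_table,
                  ggplot2::aes(x = stats::reorder(.data$trait, .data$qst),
                               y = .data$qst, colour = .data$site)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = pmax(.data$qst - .data$se, 0),
                                          ymax = pmin(.data$qst + .data$se, 1)),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(Q[ST])) +
    ggplot2::theme_minimal()
}
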