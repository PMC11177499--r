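#' Tidy a REML fit into a tibble of variance parameters
#'
#' One row per variance parameter with its estimate, asymptotic standard
#' error (square root of the inverse average-information diagonal) and a
#' boundary flag. With `effects = "fixed"` the fixed-effect solutions (BLUEs)
#' are returned instead.
#'
#' @param x A `qg_fit`.
#' @param effects `"varcomp"` (default) or `"fixed"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.qg_fit <- function(x, effects = c("varcomp", "fixed"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") {
    return(tibble::tibble(
      term = names(x$beta),
      estimate = unname(x$beta),
      std.error = sqrt(pmax(diag(x$beta_cov), 0))
    ))
  }
  tibble::tibble(
    term = names(x$theta),
    estimate = unname(x$theta),
    std.error = sqrt(pmax(diag(x$vc_covariance), 0)),
    boundary = unname(x$boundary)
  )
}

#' Glance at a REML fit
#'
#' @param x A `qg_fit`.
#' @param ... Unused.
#' @return One-row tibble: `nobs`, `n_fixed`, `n_varpar`, `logLik`, `AIC`,
#'   `converged`, `iterations`.
#' @export
glance.qg_fit <- function(x, ...) {
  tibble::tibble(
    nobs = x$n, n_fixed = x$p, n_varpar = x$npar,
    logLik = x$loglik, AIC = x$aic,
    converged = x$converged, iterations = x$iterations
  )
}

#' Tidy a cross-validation report
#'
#' @param x A `qg_cv`.
#' @param ... Unused.
#' @return The per-fold tibble (`fold`, `n_test`, `correlation`, `h2`,
#'   `converged`).
#' @export
tidy.qg_cv <- function(x, ...) {
  x$per_fold
}

#' Glance at a cross-validation report
#'
#' @param x A `qg_cv`.
#' @param ... Unused.
#' @return One-row tibble: `trait`, `model_variant`, `site`, `k`, `pa`,
#'   `pa_se`, `acc`.
#' @export
glance.qg_cv <- function(x, ...) {
  tibble::tibble(
    trait = x$trait, model_variant = x$model_variant, site = x$site,
    k = x$k, pa = x$pa, pa_se = x$pa_se, acc = x$acc
  )
}

#' Genetic-parameter report across traits
#'
#' Fits the per-site univariate model for each trait under one model variant
#' and assembles the classical report table: additive and residual variance
#' (with SEs) and narrow-sense heritability (with delta-method SE) per trait.
#'
#' @param trial A [trial_data()] object.
#' @param traits Trait names (default: all).
#' @param site Site to analyse.
#' @param model `"A"` or `"B"`.
#' @param ... Passed to [reml_fit()].
#' @return Tibble: `trait`, `model`, `site`, `sigma2_A`, `se_A`, `sigma2_e`,
#'   `se_e`, `h2`, `se_h2`, `converged`.
#' @export
parameter_report <- function(trial, traits = NULL, site = NULL,
                             model = c("B", "A"), ...) {
  model <- match.arg(model)
  traits <- traits %||% trial$traits
  purrr::map_dfr(traits, function(tr) {
    fit <- fit_univariate(trial, tr, site = site, model = model, ...)
    td <- tidy(fit)
    h <- heritability(fit, site = if ("sigma2_e" %in% names(fit$theta)) NULL
                      else site)
    e_name <- grep("^sigma2_e", td$term, value = TRUE)[1]
    tibble::tibble(
      trait = tr, model = model, site = site %||% "all",
      sigma2_A = td$estimate[td$term == "sigma2_A"],
      se_A = td$std.error[td$term == "sigma2_A"],
      sigma2_e = td$estimate[td$term == e_name],
      se_e = td$std.error[td$term == e_name],
      h2 = h$h2, se_h2 = h$se, converged = fit$converged
    )
  })
}
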