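#' Fit the standard single-trait animal model at one site
#'
#' Convenience driver for the per-site univariate evaluation: fixed block
#' effects (and a population fixed effect under model B), a pedigree additive
#' effect, and a homogeneous residual. Narrow-sense heritability at the site
#' follows as \eqn{h^2 = \sigma^2_A / (\sigma^2_A + \sigma^2_e)} via
#' [heritability()].
#'
#' @param trial A [trial_data()] object.
#' @param trait Trait column name.
#' @param site Site label to analyse (required when the trial has several
#'   sites; per-site analysis is the default reporting unit).
#' @param model `"A"` (population structure ignored) or `"B"` (population
#'   fixed effect included).
#' @param population_random Fit population as a random term instead (used for
#'   Qst); incompatible with `model = "B"`.
#' @param predict_ids Unphenotyped pedigree ids that must receive breeding
#'   values (see [build_design()]).
#' @param ... Passed to [reml_fit()] (`tol`, `max_iter`, `start_values`, ...).
#' @return A `qg_fit`, with `$model_variant`, `$trait` and `$site` recorded.
#' @export
fit_univariate <- function(trial, trait, site = NULL, model = c("B", "A"),
                           population_random = FALSE, predict_ids = NULL, ...) {
  model <- match.arg(model)
  sub <- subset_site(trial, site)
  multi_site <- dplyr::n_distinct(sub$data$site) > 1
  fixed <- c("intercept",
             if (model == "B" && !population_random) "population",
             if (multi_site) "site",
             "block")
  random <- c("additive", if (population_random) "population")
  spec <- model_spec(trait, fixed = fixed, random = random,
                     residual = if (multi_site) "by_site" else "homogeneous")
  fit <- reml_fit(build_design(sub, spec, predict_ids = predict_ids), ...)
  fit$model_variant <- model
  fit$trait <- trait
  fit$site <- site %||% "all"
  fit
}

#' Fit a two-trait animal model for additive genetic correlation
#'
#' Bivariate analysis of two traits measured on the same trees (jointly
#' observed rows), with a 2x2 additive genetic covariance matrix
#' \eqn{\{\sigma^2_{a1}, \sigma_{a12}, \sigma^2_{a2}\}} over the pedigree and
#' an unstructured 2x2 residual covariance. The additive genetic correlation
#' is then \eqn{r_a = \sigma_{a12} / \sqrt{\sigma^2_{a1}\sigma^2_{a2}}} via
#' [genetic_correlation()].
#'
#' @inheritParams fit_univariate
#' @param traits Character vector of exactly two trait names.
#' @export
fit_bivariate <- function(trial, traits, site = NULL, model = c("B", "A"), ...) {
  model <- match.arg(model)
  stopifnot(length(traits) == 2)
  sub <- subset_site(trial, site)
  multi_site <- dplyr::n_distinct(sub$data$site) > 1
  fixed <- c("intercept", if (model == "B") "population",
             if (multi_site) "site", "block")
  spec <- model_spec(traits, fixed = fixed, random = "additive",
                     residual = "unstructured_traits", genetic = "cov2_traits")
  fit <- reml_fit(build_design(sub, spec), ...)
  fit$model_variant <- model
  fit$trait <- paste(traits, collapse = "+")
  fit$site <- site %||% "all"
  fit
}

#' Fit the across-site (type-B) model for one trait
#'
#' Treats the same trait measured at two sites as two correlated responses:
#' site-specific additive variances \eqn{\sigma^2_{a1}, \sigma^2_{a2}} with
#' cross-site additive covariance \eqn{\sigma_{a12}} over the pedigree, and
#' site-specific residual variances with zero cross-site residual covariance
#' (no tree grows at both sites). The type-B genetic correlation
#' \eqn{r_B = \sigma_{a12}/\sqrt{\sigma^2_{a1}\sigma^2_{a2}}} follows via
#' [type_b_correlation()]; values near 1 mean negligible genotype-by-
#' environment interaction.
#'
#' @inheritParams fit_univariate
#' @export
fit_type_b <- function(trial, trait, model = c("B", "A"), ...) {
  model <- match.arg(model)
  nsite <- dplyr::n_distinct(trial$data$site)
  if (nsite != 2) {
    stop("type-B analysis needs exactly 2 sites, got ", nsite, call. = FALSE)
  }
  fixed <- c("intercept", if (model == "B") "population", "site", "block")
  spec <- model_spec(trait, fixed = fixed, random = "additive",
                     residual = "by_site", genetic = "cov2_sites")
  fit <- reml_fit(build_design(trial, spec), ...)
  fit$model_variant <- model
  fit$trait <- trait
  fit$site <- "both"
  fit
}

#' Fit the joint-site model with a site-by-additive interaction
#'
#' The classical joint analysis: one additive variance shared by both sites
#' plus an independent site-by-genotype interaction variance
#' \eqn{\sigma^2_{SG}} (covariance \eqn{\sigma^2_{SG} (I \otimes A)}) and
#' site-specific residuals. Equivalent to the type-B parametrization when the
#' additive variance is site-homogeneous, with
#' \eqn{r_B = \sigma^2_A / (\sigma^2_A + \sigma^2_{SG})}.
#'
#' @inheritParams fit_univariate
#' @param population_site Also include the population-by-site fixed
#'   interaction (off by default; screening on trials of this design found it
#'   negligible).
#' @export
fit_joint_site <- function(trial, trait, model = c("B", "A"),
                           population_site = FALSE, ...) {
  model <- match.arg(model)
  fixed <- c("intercept", if (model == "B") "population", "site", "block",
             if (population_site && model == "B") "population_site")
  spec <- model_spec(trait, fixed = fixed,
                     random = c("additive", "site_additive"),
                     residual = "by_site")
  fit <- reml_fit(build_design(trial, spec), ...)
  fit$model_variant <- model
  fit$trait <- trait
  fit$site <- "joint"
  fit
}

subset_site <- function(trial, site) {
  if (is.null(site)) return(trial)
  keep <- as.character(trial$data$site) == as.character(site)
  if (!any(keep)) stop("no observations at site '", site, "'", call. = FALSE)
  trial$data <- trial$data[keep, , drop = FALSE]
  trial
}

#' Wald F-test of a fixed term
#'
#' Incremental Wald test of all contrast columns of one fixed term,
#' conditional on every other fixed term, using the REML-estimated fixed-
#' effect covariance \eqn{(X'V^{-1}X)^{-1}}. The denominator degrees of
#' freedom use the residual approximation `n - rank(X)`; this is adequate for
#' designs with many families but is not a Kenward-Roger-style adjustment.
#'
#' @param fit A `qg_fit`.
#' @param term Fixed term name (e.g. `"population"`).
#' @return A one-row tibble with `statistic` (F), `num_df`, `den_df`,
#'   `p.value`.
#' @export
wald_test <- function(fit, term = "population") {
  stopifnot(inherits(fit, "qg_fit"))
  assign <- fit$design$assign
  if (!term %in% assign) {
    if (term %in% fit$design$spec$fixed) {
      stop("fixed term '", term, "' has no estimable contrast (0 numerator df)",
           call. = FALSE)
    }
    stop("term '", term, "' is not a fitted fixed effect", call. = FALSE)
  }
  idx <- which(assign == term)
  b <- fit$beta[idx]
  Vb <- fit$beta_cov[idx, idx, drop = FALSE]
  r <- length(idx)
  Fstat <- as.numeric(crossprod(b, solve(Vb, b))) / r
  den_df <- fit$n - fit$p
  tibble::tibble(
    term = term, statistic = Fstat, num_df = r, den_df = den_df,
    p.value = stats::pf(Fstat, r, den_df, lower.tail = FALSE)
  )
}
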