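#' Delta-method (Taylor-series) standard error
#'
#' Standard error of a smooth function of the variance-component estimates,
#' \eqn{se = \sqrt{g' V g}} with \eqn{g} the gradient of the function at the
#' estimates and \eqn{V} their asymptotic covariance. The gradient may be
#' supplied analytically (a numeric vector) or as a function of the parameter
#' vector, in which case it is obtained by central finite differences.
#'
#' @param f Either a numeric gradient vector, or a function
#'   `f(estimates) -> scalar` to be differentiated numerically.
#' @param estimates Parameter estimates (needed when `f` is a function).
#' @param vc_covariance Covariance matrix of the estimates (from a `qg_fit`'s
#'   `$vc_covariance`).
#' @return The standard error (nonnegative scalar).
#' @examples
#' delta_method_se(c(1, 0), vc_covariance = diag(c(4, 9))) # identity in x1: 2
#' @export
delta_method_se <- function(f, estimates = NULL, vc_covariance) {
  V <- as.matrix(vc_covariance)
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("vc_covariance is not positive semi-definite", call. = FALSE)
  }
  g <- if (is.function(f)) {
    stopifnot(!is.null(estimates))
    vapply(seq_along(estimates), function(k) {
      h <- 1e-6 * max(abs(estimates[k]), 1e-6)
      up <- estimates; up[k] <- up[k] + h
      dn <- estimates; dn[k] <- dn[k] - h
      (f(up) - f(dn)) / (2 * h)
    }, numeric(1))
  } else {
    as.numeric(f)
  }
  stopifnot(length(g) == ncol(V))
  sqrt(max(as.numeric(crossprod(g, V %*% g)), 0))
}

#' Narrow-sense heritability from fitted variance components
#'
#' \eqn{h^2 = \hat\sigma^2_A / (\hat\sigma^2_A + \hat\sigma^2_e)}, the
#' per-site parametrization in which the phenotypic variance is the sum of
#' the additive and residual variances of that site. When the fit carries a
#' site-by-additive interaction variance it can optionally be added to the
#' denominator (`include_interaction = TRUE`). The standard error is the
#' delta method with the analytic gradient
#' \eqn{(\sigma^2_e, -\sigma^2_A)/\sigma^4_P}.
#'
#' @param fit A `qg_fit` with an additive variance (`sigma2_A`).
#' @param site Site label selecting the residual variance when the fit has
#'   site-specific residuals; not needed for single-site fits.
#' @param include_interaction Add `sigma2_SG` (if present) to the phenotypic
#'   variance.
#' @return One-row tibble: `trait`, `site`, `model`, `h2`, `se`.
#' @export
heritability <- function(fit, site = NULL, include_interaction = FALSE) {
  stopifnot(inherits(fit, "qg_fit"))
  th <- fit$theta
  if (!"sigma2_A" %in% names(th)) {
    stop("fit has no single additive variance 'sigma2_A'; use ",
         "genetic_correlation()/type_b_correlation() for 2x2 structures",
         call. = FALSE)
  }
  e_name <- if ("sigma2_e" %in% names(th)) "sigma2_e" else {
    if (is.null(site)) stop("site-specific residuals: supply `site`",
                            call. = FALSE)
    paste0("sigma2_e.", site)
  }
  if (!e_name %in% names(th)) stop("no residual variance for site '", site, "'",
                                   call. = FALSE)
  use <- c("sigma2_A", e_name,
           if (include_interaction && "sigma2_SG" %in% names(th)) "sigma2_SG")
  a <- th[["sigma2_A"]]
  ptot <- sum(th[use])
  if (ptot <= 0) stop("phenotypic variance is zero", call. = FALSE)
  grad <- stats::setNames(rep(-a / ptot^2, length(use)), use)
  grad["sigma2_A"] <- (ptot - a) / ptot^2
  se <- delta_method_se(grad, vc_covariance = fit$vc_covariance[use, use])
  tibble::tibble(trait = fit$trait %||% fit$design$responses[1],
                 site = site %||% (fit$site %||% "all"),
                 model = fit$model_variant %||% NA_character_,
                 h2 = a / ptot, se = se)
}

#' @describeIn heritability Pure arithmetic on (vectors of) printed variance
#'   components, for re-deriving heritabilities from published tables.
#' @param sigma2_A,sigma2_e Additive and residual variance estimates.
#' @export
h2_from_components <- function(sigma2_A, sigma2_e) {
  sigma2_A / (sigma2_A + sigma2_e)
}

# correlation + delta SE from a (v1, cov, v2) triple in a fit
cov2_correlation <- function(fit, prefix) {
  th <- fit$theta
  nm <- names(th)
  vi <- grep(paste0("^", prefix, "\\."), nm, value = TRUE)
  cn <- grep("^sigma_A12$", nm, value = TRUE)
  if (length(vi) != 2 || length(cn) != 1) {
    stop("fit does not carry a 2x2 additive covariance structure", call. = FALSE)
  }
  v1 <- th[[vi[1]]]; v2 <- th[[vi[2]]]; cv <- th[[cn]]
  r <- cv / sqrt(v1 * v2)
  clamped <- FALSE
  if (abs(r) > 1) { r <- sign(r); clamped <- TRUE }
  use <- c(vi[1], cn, vi[2])
  grad <- c(-cv / (2 * v1 * sqrt(v1 * v2)),
            1 / sqrt(v1 * v2),
            -cv / (2 * v2 * sqrt(v1 * v2)))
  se <- delta_method_se(grad, vc_covariance = fit$vc_covariance[use, use])
  unreliable <- any(fit$boundary[c(vi, cn)])
  if (unreliable) {
    warning("an additive variance is at its boundary; the correlation SE is ",
            "unreliable", call. = FALSE)
  }
  if (clamped) {
    warning("estimated correlation outside [-1, 1]; clamped to ", r,
            call. = FALSE)
  }
  list(r = r, se = se, clamped = clamped, unreliable = unreliable)
}

#' Additive genetic correlation between two traits
#'
#' \eqn{r_a = \hat\sigma_{a12} / \sqrt{\hat\sigma^2_{a1}\hat\sigma^2_{a2}}}
#' from a bivariate fit ([fit_bivariate()]), with a delta-method standard
#' error from the analytic gradient. A negative value between two desirable
#' traits indicates a breeding trade-off.
#'
#' @param fit A bivariate `qg_fit`.
#' @return One-row tibble: `trait`, `model`, `r_a`, `se`, `boundary`.
#' @export
genetic_correlation <- function(fit) {
  stopifnot(inherits(fit, "qg_fit"))
  res <- cov2_correlation(fit, "sigma2_A")
  tibble::tibble(trait = fit$trait %||% paste(fit$design$responses, collapse = "+"),
                 model = fit$model_variant %||% NA_character_,
                 r_a = res$r, se = res$se,
                 boundary = res$clamped || res$unreliable)
}

#' Type-B genetic correlation of one trait across two sites
#'
#' Same estimator as [genetic_correlation()] with the two sites acting as
#' pseudo-traits: \eqn{r_B = \hat\sigma_{a12} /
#' \sqrt{\hat\sigma^2_{a1}\hat\sigma^2_{a2}}} where \eqn{\sigma_{a12}} is the
#' covariance of the additive effects of the same trait at the two sites.
#' Values near 1 indicate little genotype-by-environment interaction.
#'
#' @param fit A type-B `qg_fit` from [fit_type_b()].
#' @return One-row tibble: `trait`, `model`, `r_b`, `se`, `boundary`.
#' @export
type_b_correlation <- function(fit) {
  stopifnot(inherits(fit, "qg_fit"))
  res <- cov2_correlation(fit, "sigma2_A")
  tibble::tibble(trait = fit$trait %||% fit$design$responses[1],
                 model = fit$model_variant %||% NA_character_,
                 r_b = res$r, se = res$se,
                 boundary = res$clamped || res$unreliable)
}

#' Population differentiation of a quantitative trait (Qst)
#'
#' Refits the per-site model with the population term as random (variance
#' \eqn{\sigma^2_G}) alongside the pedigree additive effect, and returns
#' \deqn{Q_{ST} = \hat\sigma^2_G / (\hat\sigma^2_G + 2\hat\sigma^2_A)}
#' with a delta-method standard error. The factor 2 reflects that the
#' within-population additive variance enters through twice the additive
#' variance. Values near 0 mean populations share a common genetic mean for
#' the trait; large values mean strong among-population differentiation.
#'
#' @param trial A [trial_data()] object (>= 2 populations).
#' @param trait Trait name.
#' @param site Site to analyse.
#' @param ... Passed to [reml_fit()].
#' @return One-row tibble: `trait`, `site`, `qst`, `se`, `sigma2_G`,
#'   `sigma2_A`, `boundary`.
#' @export
qst <- function(trial, trait, site = NULL, ...) {
  sub <- subset_site(trial, site)
  npop <- dplyr::n_distinct(sub$data$population)
  if (npop < 2) stop("Qst needs >= 2 populations after filtering", call. = FALSE)
  fit <- fit_univariate(sub, trait, site = NULL, model = "A",
                        population_random = TRUE, ...)
  g <- fit$theta[["sigma2_G"]]
  a <- fit$theta[["sigma2_A"]]
  if (fit$boundary[["sigma2_G"]] && fit$boundary[["sigma2_A"]]) {
    warning("sigma2_G and sigma2_A both at the variance floor: Qst undefined",
            call. = FALSE)
    return(tibble::tibble(trait = trait, site = site %||% "all", qst = NA_real_,
                          se = NA_real_, sigma2_G = g, sigma2_A = a,
                          boundary = TRUE))
  }
  den <- g + 2 * a
  use <- c("sigma2_G", "sigma2_A")
  grad <- c(2 * a / den^2, -2 * g / den^2)
  se <- delta_method_se(grad, vc_covariance = fit$vc_covariance[use, use])
  tibble::tibble(trait = trait, site = site %||% "all",
                 qst = g / den, se = se, sigma2_G = g, sigma2_A = a,
                 boundary = any(fit$boundary[use]))
}

#' Estimated breeding values
#'
#' \eqn{EBV = \hat\mu + \hat G_{m(l)} + \hat P_l} for model B (the population
#' fixed-effect solution is added, reference level contributing 0); for model
#' A the population term is absent and \eqn{EBV = \hat\mu + \hat G_m}.
#' Every pedigree individual receives an EBV: unphenotyped members (e.g. the
#' mother trees) are predicted through the relationship matrix.
#'
#' @param fit A `qg_fit` with a single additive variance (univariate or
#'   joint-site model).
#' @param model_variant Override the variant recorded on the fit.
#' @return Tibble: `tree_id`, `trait`, `model_variant`, `population`, `ebv`.
#' @export
compute_ebv <- function(fit, model_variant = NULL) {
  stopifnot(inherits(fit, "qg_fit"))
  variant <- model_variant %||% (fit$model_variant %||% "A")
  u <- fit$u[["additive"]]
  if (is.null(u) || is.matrix(u)) {
    stop("EBVs need a fit with a single additive effect per individual",
         call. = FALSE)
  }
  mu <- unname(fit$beta["(Intercept)"])
  ids <- names(u)
  pop <- population_of(fit, ids)
  phat <- numeric(length(ids))
  if (variant == "B" && "population" %in% fit$design$assign) {
    coefs <- fit$beta[fit$design$assign == "population"]
    names(coefs) <- sub("^population", "", names(coefs))
    hit <- match(pop, names(coefs))
    phat <- ifelse(is.na(hit), 0, coefs[ifelse(is.na(hit), 1L, hit)])
  }
  tibble::tibble(
    tree_id = ids,
    trait = fit$trait %||% fit$design$responses[1],
    model_variant = variant,
    population = pop,
    ebv = mu + unname(u) + unname(phat)
  )
}

# population label for every pedigree id: phenotyped trees carry their own
# label; founders inherit the label of their offspring
population_of <- function(fit, ids) {
  map <- fit$design$tree_population
  ped <- fit$design$pedigree
  pop <- unname(map[ids])
  miss <- which(is.na(pop))
  if (length(miss) > 0) {
    kid_pop <- tibble::tibble(mother = ped$mother, pop = unname(map[ped$id])) |>
      dplyr::filter(!is.na(.data$mother), !is.na(.data$pop)) |>
      dplyr::distinct(.data$mother, .data$pop) |>
      dplyr::distinct(.data$mother, .keep_all = TRUE)
    # founders: label of their phenotyped offspring
    hit <- match(ids[miss], kid_pop$mother)
    pop[miss] <- kid_pop$pop[hit]
    # unphenotyped offspring: label of their mother's family
    still <- which(is.na(pop))
    if (length(still) > 0) {
      mom <- ped$mother[match(ids[still], ped$id)]
      pop[still] <- dplyr::coalesce(unname(map[mom]),
                                    kid_pop$pop[match(mom, kid_pop$mother)])
    }
  }
  pop
}
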