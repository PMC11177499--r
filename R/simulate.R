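#' Configure a synthetic two-site half-sib progeny trial
#'
#' Describes the data-generating process of an open-pollinated progeny trial:
#' mothers (plus-trees) are unrelated, non-inbred founders nested in
#' populations; each contributes one half-sib family whose offspring are
#' split across sites and assigned at random to blocks (single-tree plots).
#' For each trait the phenotype is
#' `grand_mean + population effect + site shift + block effect +
#' site-specific breeding value + residual`.
#'
#' Population effects are drawn `N(0, sigma2_pop)` so the theoretical
#' differentiation `Qst = sigma2_pop / (sigma2_pop + 2 sigma2_A)` is exact in
#' expectation; a fixed-means mode (`population_means`) exists for tests that
#' need a known population ordering. Genotype-by-environment structure is
#' generated at the additive level: every individual carries one breeding
#' value per (trait, site) cell, founders drawn from the factor model
#' `g_{t,j} = sd_t (sqrt(r_B_t) z_t + sqrt(1 - r_B_t) w_{t,j})` with `z` and
#' `w` standard normal vectors correlated `r_a` across traits, and offspring
#' values are `0.5 x mother + Mendelian deviation ~ N(0, 0.75 x cell
#' covariance)` (fathers unknown and unrelated). This makes the cross-site
#' additive correlation exactly `r_B_t` per trait; the implied cross-trait
#' correlation at one site, `r_a (sqrt(r_B1 r_B2) + sqrt((1-r_B1)(1-r_B2)))`,
#' is reported in the simulation truth. Because both the shared factor `z`
#' and the site deviations `w` are inherited through the pedigree, this is
#' distributionally identical to the classical additive-plus-interaction
#' formulation (shared breeding value of variance `sigma2_A r_B` plus an
#' independent pedigree-structured site deviation of variance
#' `sigma2_A (1 - r_B)`).
#'
#' @param n_populations,families_per_population,offspring_per_family Trial
#'   dimensions (offspring are split evenly across sites).
#' @param n_sites,blocks_per_site Layout; blocks are filled by random
#'   assignment within site.
#' @param traits A list of per-trait settings, each a list with `name`,
#'   `sigma2_A`, `sigma2_e` (scalar or one per site), `sigma2_pop`,
#'   `sigma2_block`, `grand_mean`, `r_B`, `site_shift` (length `n_sites`).
#' @param r_a Additive correlation between the two traits (2-trait configs).
#' @param r_e Residual correlation between the two traits within a tree.
#' @param population_means Optional matrix (population x trait) of fixed
#'   population means overriding the random draw.
#' @param missing_rate Probability that a phenotype value is missing.
#' @param seed Integer seed; every draw is reproducible from it.
#' @return An object of class `qg_sim_config`.
#' @export
sim_config <- function(n_populations = 6, families_per_population = 50,
                       offspring_per_family = 10, n_sites = 2,
                       blocks_per_site = 10,
                       traits = list(default_trait()),
                       r_a = 0, r_e = 0, population_means = NULL,
                       missing_rate = 0, seed = 1L) {
  stopifnot(n_populations >= 1, families_per_population >= 1,
            offspring_per_family >= 1, n_sites >= 1, blocks_per_site >= 1,
            abs(r_a) <= 1, abs(r_e) <= 1, length(traits) %in% 1:2,
            missing_rate >= 0, missing_rate < 1)
  traits <- lapply(traits, function(tr) {
    tr$sigma2_e <- rep(tr$sigma2_e, length.out = n_sites)
    tr$site_shift <- rep(tr$site_shift %||% 0, length.out = n_sites)
    stopifnot(tr$sigma2_A >= 0, all(tr$sigma2_e >= 0), tr$sigma2_pop >= 0,
              tr$sigma2_block >= 0, abs(tr$r_B) <= 1)
    tr
  })
  names(traits) <- vapply(traits, function(tr) tr$name, character(1))
  structure(list(
    n_populations = n_populations,
    families_per_population = families_per_population,
    offspring_per_family = offspring_per_family,
    n_sites = n_sites, blocks_per_site = blocks_per_site,
    traits = traits, r_a = r_a, r_e = r_e,
    population_means = population_means,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "qg_sim_config")
}

#' @rdname sim_config
#' @param name,sigma2_A,sigma2_e,sigma2_pop,sigma2_block,grand_mean,r_B,site_shift
#'   Per-trait generating values; see `traits`.
#' @export
default_trait <- function(name = "TRAIT", sigma2_A = 300, sigma2_e = 600,
                          sigma2_pop = 0, sigma2_block = 90, grand_mean = 100,
                          r_B = 1, site_shift = NULL) {
  list(name = name, sigma2_A = sigma2_A, sigma2_e = sigma2_e,
       sigma2_pop = sigma2_pop, sigma2_block = sigma2_block,
       grand_mean = grand_mean, r_B = r_B, site_shift = site_shift)
}

#' Desk-scale preset emulating a southern Swedish spruce progeny trial
#'
#' Two sites, 6 populations, 50 open-pollinated families per population, 10
#' offspring per family (3,000 trees), with two traits on the scale of a
#' growth trait (diameter-like: `sigma2_A = 300`, `sigma2_e = 600`, so
#' theoretical `h2 = 0.33`, strong population differentiation `Qst = 0.20`)
#' and a wood-density-like trait (`sigma2_A = 1400`, `sigma2_e = 150`,
#' `h2 = 0.90`, weak differentiation `Qst = 0.04`). The additive correlation
#' between them is -0.6 (the growth/wood-quality trade-off), cross-site
#' additive correlations 0.95 and 0.85.
#'
#' @param seed Seed stored in the config.
#' @return A [sim_config()].
#' @export
spruce_preset <- function(seed = 1L) {
  qst_to_pop <- function(q, s2a) 2 * s2a * q / (1 - q)
  growth <- default_trait(
    name = "DBH", sigma2_A = 300, sigma2_e = 600,
    sigma2_pop = qst_to_pop(0.20, 300), sigma2_block = 90,
    grand_mean = 150, r_B = 0.95, site_shift = c(0, 15)
  )
  dens <- default_trait(
    name = "DENS", sigma2_A = 1400, sigma2_e = 150,
    sigma2_pop = qst_to_pop(0.04, 1400), sigma2_block = 155,
    grand_mean = 420, r_B = 0.85, site_shift = c(0, 20)
  )
  sim_config(n_populations = 6, families_per_population = 50,
             offspring_per_family = 10, n_sites = 2, blocks_per_site = 10,
             traits = list(growth, dens), r_a = -0.6, r_e = -0.2, seed = seed)
}

#' Simulate a progeny trial with known variance components
#'
#' Draws a dataset from a [sim_config()] and returns it together with its
#' pedigree and the simulation truth (true breeding values per trait and
#' site, population effects, and the theoretical parameter values implied by
#' the configuration), so that estimation can be validated against known
#' targets.
#'
#' @param config A [sim_config()].
#' @param seed Optional override of `config$seed`.
#' @return A list of class `qg_sim` with elements `trial` (a [trial_data()]
#'   object), `pedigree`, and `truth` (list: `breeding_values` tibble,
#'   `population_effects`, `h2`, `qst`, `r_B`, `r_a_cross_site`,
#'   `r_a_within_site` tibbles/values).
#' @export
simulate_trial <- function(config, seed = NULL) {
  stopifnot(inherits(config, "qg_sim_config"))
  set.seed(seed %||% config$seed)
  np <- config$n_populations
  nf <- config$families_per_population
  no <- config$offspring_per_family
  ns <- config$n_sites
  tr <- config$traits
  nt <- length(tr)

  pop_labels <- if (np == 6) {
    c("ALP", "CEU", "CSE", "CSE-ALP", "NPL", "RusBal")
  } else {
    sprintf("POP%02d", seq_len(np))
  }

  # cell covariance of the additive value across (trait, site) cells
  cell <- cell_covariance(config)
  ncell <- nrow(cell$sigma)

  mothers <- tibble::tibble(
    id = sprintf("M%s_F%03d", rep(pop_labels, each = nf), seq_len(np * nf)),
    population = rep(pop_labels, each = nf)
  )
  n_mother <- nrow(mothers)
  a_mother <- rmvn(n_mother, cell$sigma)

  n_off <- n_mother * no
  off_mother <- rep(seq_len(n_mother), each = no)
  mend <- rmvn(n_off, 0.75 * cell$sigma)
  a_off <- 0.5 * a_mother[off_mother, , drop = FALSE] + mend

  offspring <- tibble::tibble(
    tree_id = sprintf("T%05d", seq_len(n_off)),
    mother_id = mothers$id[off_mother],
    population = mothers$population[off_mother],
    site = cell$site_names[rep_len(seq_len(ns), n_off)],
    block = NA_character_
  )
  for (s in cell$site_names) {
    in_s <- offspring$site == s
    offspring$block[in_s] <- sprintf("B%02d", sample.int(config$blocks_per_site,
                                                         sum(in_s),
                                                         replace = TRUE))
  }

  # population effects per trait
  pop_eff <- matrix(0, np, nt, dimnames = list(pop_labels, names(tr)))
  if (!is.null(config$population_means)) {
    pm <- config$population_means
    pop_eff[] <- pm[seq_len(np), seq_len(nt)]
  } else {
    for (t in seq_len(nt)) {
      pop_eff[, t] <- rnorm(np, 0, sqrt(tr[[t]]$sigma2_pop))
    }
  }

  # block effects per (trait, site, block)
  blk_eff <- array(
    rnorm(nt * ns * config$blocks_per_site),
    dim = c(config$blocks_per_site, ns, nt)
  )
  for (t in seq_len(nt)) blk_eff[, , t] <- blk_eff[, , t] * sqrt(tr[[t]]$sigma2_block)

  # residuals: cross-trait correlation r_e within tree, site-specific scale
  site_idx <- match(offspring$site, cell$site_names)
  blk_idx <- as.integer(sub("^B", "", offspring$block))
  Re <- matrix(config$r_e, nt, nt); diag(Re) <- 1
  e_raw <- rmvn(n_off, Re)

  phen <- offspring
  for (t in seq_len(nt)) {
    trt <- tr[[t]]
    g_site <- a_off[cbind(seq_len(n_off), cell$cell_of(t, site_idx))]
    e <- e_raw[, t] * sqrt(trt$sigma2_e[site_idx])
    yv <- trt$grand_mean + trt$site_shift[site_idx] +
      blk_eff[cbind(blk_idx, site_idx, t)] +
      pop_eff[cbind(match(offspring$population, pop_labels), t)] +
      g_site + e
    if (config$missing_rate > 0) {
      yv[stats::runif(n_off) < config$missing_rate] <- NA_real_
    }
    phen[[trt$name]] <- yv
  }

  ped_tbl <- tibble::tibble(
    individual = c(mothers$id, offspring$tree_id),
    mother = c(rep(NA_character_, n_mother), offspring$mother_id),
    father = NA_character_
  )
  trial <- trial_data(phen, ped_tbl)

  bv <- dplyr::bind_cols(
    tibble::tibble(id = c(mothers$id, offspring$tree_id)),
    rbind(a_mother, a_off) |>
      as.data.frame() |>
      stats::setNames(cell$cell_names) |>
      tibble::as_tibble()
  )
  truth <- list(
    breeding_values = bv,
    population_effects = pop_eff,
    h2 = purrr::map_dfr(seq_len(nt), function(t) tibble::tibble(
      trait = names(tr)[t], site = cell$site_names,
      h2 = tr[[t]]$sigma2_A / (tr[[t]]$sigma2_A + tr[[t]]$sigma2_e)
    )),
    qst = purrr::map_dbl(tr, function(x)
      x$sigma2_pop / (x$sigma2_pop + 2 * x$sigma2_A)),
    r_B = purrr::map_dbl(tr, "r_B"),
    r_a_within_site = cell$r_a_within_site,
    sigma2_A = purrr::map_dbl(tr, "sigma2_A"),
    sigma2_e = purrr::map(tr, "sigma2_e"),
    sigma2_pop = purrr::map_dbl(tr, "sigma2_pop"),
    config = config
  )
  structure(list(trial = trial, pedigree = trial$pedigree, truth = truth),
            class = "qg_sim")
}

# covariance of the (trait x site) additive cells implied by the factor
# model; also returns the implied within-site cross-trait correlation
cell_covariance <- function(config) {
  tr <- config$traits
  nt <- length(tr)
  ns <- config$n_sites
  site_names <- sprintf("S%d", seq_len(ns))
  # loading representation: g_{t,j} = sd_t (sqrt(rB_t) z_t + sqrt(1-rB_t) w_{t,j})
  # with Cov(z_t, z_t') = Cov(w_{t,j}, w_{t',j}) = r_a
  Ra <- matrix(config$r_a, nt, nt); diag(Ra) <- 1
  cells <- expand.grid(trait = seq_len(nt), site = seq_len(ns))
  ncell <- nrow(cells)
  S <- matrix(0, ncell, ncell)
  for (i in seq_len(ncell)) {
    for (j in seq_len(ncell)) {
      t1 <- cells$trait[i]; s1 <- cells$site[i]
      t2 <- cells$trait[j]; s2 <- cells$site[j]
      b1 <- tr[[t1]]$r_B; b2 <- tr[[t2]]$r_B
      # loadings give correlation 1 on the diagonal, r_B for the same trait
      # across sites, and the attenuated r_a across traits
      rho <- if (t1 == t2 && s1 == s2) 1 else {
        sqrt(b1 * b2) + (s1 == s2) * sqrt((1 - b1) * (1 - b2))
      }
      S[i, j] <- sqrt(tr[[t1]]$sigma2_A * tr[[t2]]$sigma2_A) * Ra[t1, t2] * rho
    }
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(ev)) {
    stop("trait/site additive covariance implied by the config is not ",
         "positive semi-definite", call. = FALSE)
  }
  cell_names <- sprintf("%s.%s", names(tr)[cells$trait], site_names[cells$site])
  r_a_within <- if (nt == 2) {
    b1 <- tr[[1]]$r_B; b2 <- tr[[2]]$r_B
    config$r_a * (sqrt(b1 * b2) + sqrt((1 - b1) * (1 - b2)))
  } else NA_real_
  list(
    sigma = S, cell_names = cell_names, site_names = site_names,
    cell_of = function(t, s) (s - 1L) * nt + t,
    r_a_within_site = r_a_within
  )
}

rmvn <- function(n, sigma) {
  p <- nrow(sigma)
  ev <- eigen(sigma, symmetric = TRUE)
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p) %*% t(ev$vectors)
  matrix(rnorm(n * p), n, p) %*% rt
}

#' @export
print.qg_sim_config <- function(x, ...) {
  cat("<qg_sim_config>", x$n_populations, "populations x",
      x$families_per_population, "families x", x$offspring_per_family,
      "offspring;", x$n_sites, "site(s)\n")
  for (tr in x$traits) {
    cat(sprintf("  %s: sigma2_A=%g sigma2_e=%s sigma2_pop=%g (Qst=%.3f) r_B=%g\n",
                tr$name, tr$sigma2_A, paste(tr$sigma2_e, collapse = "/"),
                tr$sigma2_pop,
                tr$sigma2_pop / (tr$sigma2_pop + 2 * tr$sigma2_A), tr$r_B))
  }
  invisible(x)
}
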