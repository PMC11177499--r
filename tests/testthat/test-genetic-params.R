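test_that("heritability arithmetic matches published worked examples", {
  # growth trait: 92.578 / (92.578 + 203.693) = 0.312
  expect_lt(abs(h2_from_components(92.578, 203.693) - 0.312), 0.001)
  # density trait: 1414.590 / (1414.590 + 151.082) = 0.903
  expect_lt(abs(h2_from_components(1414.590, 151.082) - 0.903), 0.001)
  # no additive variance -> zero heritability
  expect_equal(h2_from_components(0, 100), 0)
})

test_that("heritability from a fit carries a finite delta-method SE", {
  hs <- make_halfsib_trial(nf = 80, no = 5, seed = 101)
  fit <- fit_univariate(hs$trial, "Y", model = "A")
  h <- heritability(fit)
  a <- fit$theta[["sigma2_A"]]; e <- fit$theta[["sigma2_e"]]
  expect_equal(h$h2, a / (a + e))
  expect_true(is.finite(h$se) && h$se > 0)
  # numeric gradient route through the same covariance agrees
  se_num <- delta_method_se(function(th) th[1] / (th[1] + th[2]),
                            estimates = c(a, e),
                            vc_covariance = fit$vc_covariance)
  expect_equal(h$se, se_num, tolerance = 1e-5)
})

test_that("delta-method SE handles identity, zero-covariance and analytic
           vs numeric gradients", {
  expect_equal(delta_method_se(c(1, 0), vc_covariance = diag(c(4, 9))), 2)
  expect_equal(delta_method_se(c(0, 0), vc_covariance = diag(2)), 0)
  expect_equal(delta_method_se(function(x) x[1], estimates = 1,
                               vc_covariance = matrix(4)), 2,
               tolerance = 1e-6)
  # h2 gradient: analytic vs central differences to < 1e-6 relative
  a <- 92.578; e <- 203.693
  grad_an <- c(e, -a) / (a + e)^2
  grad_num <- vapply(1:2, function(k) {
    h <- 1e-4
    up <- c(a, e); dn <- c(a, e)
    up[k] <- up[k] + h; dn[k] <- dn[k] - h
    (up[1] / sum(up) - dn[1] / sum(dn)) / (2 * h)
  }, numeric(1))
  expect_equal(grad_an, grad_num, tolerance = 1e-6)
  expect_error(delta_method_se(c(1, 1), vc_covariance = matrix(c(1, 2, 2, 1), 2)),
               "positive semi-definite")
})

test_that("correlation estimators hit the algebraic corner cases", {
  sim <- simulate_trial(sim_config(
    n_populations = 2, families_per_population = 40, offspring_per_family = 6,
    n_sites = 2, blocks_per_site = 2,
    traits = list(default_trait(name = "Y", r_B = 0)), seed = 7
  ))
  # independent site effects -> r_B near 0 (variances may sit on a boundary)
  fit0 <- fit_type_b(sim$trial, "Y", model = "A")
  r0 <- suppressWarnings(type_b_correlation(fit0))
  expect_lt(abs(r0$r_b), 3 * r0$se + 0.05)

  # algebraic corners on a constructed fit: a covariance equal to the
  # geometric mean of the variances is correlation 1; zero covariance is 0
  fake_fit <- function(v1, cv, v2) {
    nm <- c("sigma2_A.T1", "sigma_A12", "sigma2_A.T2")
    structure(list(
      theta = stats::setNames(c(v1, cv, v2), nm),
      vc_covariance = matrix(0, 3, 3, dimnames = list(nm, nm)),
      boundary = stats::setNames(rep(FALSE, 3), nm),
      trait = "T1+T2", model_variant = "A"
    ), class = "qg_fit")
  }
  r_one <- genetic_correlation(fake_fit(4, sqrt(4 * 9), 9))
  expect_equal(r_one$r_a, 1)
  expect_equal(r_one$se, 0)
  expect_equal(genetic_correlation(fake_fit(4, 0, 9))$r_a, 0)

  # a simulated strongly correlated pair is recovered near +0.9
  sim2 <- simulate_trial(sim_config(
    n_populations = 1, families_per_population = 60, offspring_per_family = 6,
    n_sites = 1, blocks_per_site = 2,
    traits = list(default_trait(name = "Y1"),
                  default_trait(name = "Y2", sigma2_A = 100, sigma2_e = 200,
                                grand_mean = 20)),
    r_a = 0.9, r_e = 0.1, seed = 27
  ))
  fit1 <- fit_bivariate(sim2$trial, c("Y1", "Y2"), model = "A")
  r1 <- suppressWarnings(genetic_correlation(fit1))
  expect_lt(abs(r1$r_a - 0.9), 3 * r1$se + 0.05)
})

test_that("Qst machinery matches its defining ratio and recovers truth
           qualitatively", {
  # sigma2_G = 2 sigma2_A gives Qst = 0.5 by definition
  expect_equal(200 / (200 + 2 * 100), 0.5)

  sim <- simulate_trial(sim_config(
    n_populations = 8, families_per_population = 25, offspring_per_family = 6,
    n_sites = 1, blocks_per_site = 2,
    traits = list(default_trait(name = "Y", sigma2_A = 300, sigma2_e = 600,
                                sigma2_pop = 2 * 300 * 0.2 / 0.8)),
    seed = 17
  ))
  q <- qst(sim$trial, "Y")
  expect_equal(sim$truth$qst[["Y"]], 0.2, tolerance = 1e-12)
  expect_true(q$qst >= 0 && q$qst <= 1)
  expect_lt(abs(q$qst - 0.2), 4 * q$se)
  expect_error(qst(make_halfsib_trial(nf = 6, no = 2)$trial, "Y"),
               ">= 2 populations")
})

test_that("EBVs follow mu + G (+P) and shrink to the mean for flat data", {
  hs <- make_halfsib_trial(nf = 10, no = 4, seed = 111)
  tr <- hs$trial
  # all phenotypes equal: variance is degenerate by design, so nudge by a
  # tiny residual and expect the additive solutions to be ~0
  set.seed(1); tr$data$Y <- 50 + rnorm(40, 0, 1e-3)
  fit <- fit_univariate(tr, "Y", model = "A", max_iter = 60)
  ebv <- compute_ebv(fit)
  expect_lt(max(abs(ebv$ebv - fit$beta[["(Intercept)"]])), 0.01)

  # model B minus model A differs by a population-constant shift plus
  # re-shrinkage; EBV population means follow the simulated population means
  sim <- simulate_trial(sim_config(
    n_populations = 4, families_per_population = 30, offspring_per_family = 6,
    n_sites = 1, blocks_per_site = 2,
    traits = list(default_trait(name = "Y", sigma2_pop = 400)), seed = 13
  ))
  fitB <- fit_univariate(sim$trial, "Y", model = "B")
  ebvB <- compute_ebv(fitB)
  pop_means <- tapply(ebvB$ebv, ebvB$population, mean)
  truth <- sim$truth$population_effects[names(pop_means), "Y"]
  expect_equal(order(pop_means), order(truth))
})

test_that("an unphenotyped half-sib gets the MME-predicted family value", {
  hs <- make_halfsib_trial(nf = 25, no = 5, seed = 121)
  tr <- hs$trial
  drop_id <- tr$data$tree_id[1]
  kept <- tr$data$tree_id != drop_id
  tr$data <- tr$data[kept, , drop = FALSE]
  fit <- fit_univariate(tr, "Y", model = "A", predict_ids = drop_id)
  ebv <- compute_ebv(fit)
  expect_true(drop_id %in% ebv$tree_id)
  # dense oracle: u = s2A * A[drop, obs] V^-1 (y - X beta)
  d <- fit$design
  A <- relationship_matrix(d$pedigree)
  idx <- match(d$rows$tree_id, d$pedigree$id)
  V <- fit$theta[["sigma2_A"]] * A[idx, idx] +
    fit$theta[["sigma2_e"]] * diag(d$n)
  pred <- fit$theta[["sigma2_A"]] *
    A[drop_id, idx] %*% solve(V, d$y - d$X %*% fit$beta)
  expect_equal(unname(fit$u$additive[drop_id]), as.numeric(pred),
               tolerance = 1e-6)
})

test_that("the population Wald test behaves at its corners", {
  sim <- simulate_trial(sim_config(
    n_populations = 5, families_per_population = 12, offspring_per_family = 5,
    n_sites = 1, blocks_per_site = 2,
    traits = list(default_trait(name = "Y", sigma2_pop = 900)), seed = 19
  ))
  fit <- fit_univariate(sim$trial, "Y", model = "B")
  w <- wald_test(fit, "population")
  expect_equal(w$num_df, 4)
  expect_equal(w$den_df, fit$n - fit$p)
  # a +1 SD population shift regime: overwhelming evidence
  expect_lt(w$p.value, 1e-3)

  expect_error(wald_test(fit, "banana"), "not a fitted fixed effect")
  # single-population data: no estimable contrast (0 numerator df)
  hs <- make_halfsib_trial(nf = 10, no = 3, seed = 23)
  fitA <- fit_univariate(hs$trial, "Y", model = "B")
  expect_error(wald_test(fitA, "population"), "no estimable contrast|not a fitted")
})
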