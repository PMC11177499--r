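test_that("animal model equals the reparametrized family model on balanced
           half-sib data", {
  hs <- make_halfsib_trial(nf = 60, no = 5, seed = 21)
  fit <- fit_univariate(hs$trial, "Y", model = "A")
  expect_true(fit$converged)

  # oracle 1: lme4 family model, sigma2_f = sigma2_A/4,
  # sigma2_w = sigma2_e + 0.75 sigma2_A gives an identical marginal model
  lm4 <- lme4::lmer(Y ~ 1 + (1 | mother_id), data = hs$phen, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lm4))
  expect_equal(fit$loglik, as.numeric(stats::logLik(lm4)), tolerance = 1e-9)
  expect_equal(unname(fit$theta["sigma2_A"]), 4 * vc$vcov[1], tolerance = 1e-4)
  expect_equal(unname(fit$theta["sigma2_e"] + 0.75 * fit$theta["sigma2_A"]),
               vc$vcov[2], tolerance = 1e-4)

  # oracle 2: direct dense restricted likelihood at the mapped optimum
  ll_dense <- family_model_loglik(hs$phen$Y, hs$phen$mother_id,
                                  s2f = unname(fit$theta["sigma2_A"]) / 4,
                                  s2w = unname(fit$theta["sigma2_e"] +
                                                 0.75 * fit$theta["sigma2_A"]))
  expect_equal(fit$loglik, ll_dense, tolerance = 1e-6)
})

test_that("REML recovers generating variance components across replicates", {
  # desk-scale recovery: mean estimate within 3 Monte-Carlo SEs of truth
  reps <- 12
  est <- t(vapply(seq_len(reps), function(s) {
    hs <- make_halfsib_trial(nf = 100, no = 6, sigma2_A = 300, sigma2_e = 600,
                             seed = 300 + s)
    fit <- fit_univariate(hs$trial, "Y", model = "A")
    fit$theta[c("sigma2_A", "sigma2_e")]
  }, numeric(2)))
  for (j in 1:2) {
    truth <- c(300, 600)[j]
    mc_se <- stats::sd(est[, j]) / sqrt(reps)
    expect_lt(abs(mean(est[, j]) - truth), 3 * mc_se + 1e-9)
  }
})

test_that("the log-likelihood trace is non-decreasing (monotone halving)", {
  sim <- simulate_trial(spruce_preset(seed = 31))
  fit <- fit_univariate(sim$trial, "DBH", site = "S1", model = "B")
  expect_true(all(diff(fit$trace$loglik) > -1e-10))
  fit2 <- fit_bivariate(sim$trial, c("DBH", "DENS"), site = "S1", model = "A")
  expect_true(all(diff(fit2$trace$loglik) > -1e-10))
})

test_that("refitting from the solution is a fixed point", {
  hs <- make_halfsib_trial(nf = 50, no = 4, seed = 41)
  d <- build_design(hs$trial, model_spec("Y", fixed = "intercept"))
  fit <- reml_fit(d)
  refit <- reml_fit(d, start_values = fit$theta)
  expect_equal(unname(refit$theta), unname(fit$theta), tolerance = 1e-5)
  expect_equal(refit$loglik, fit$loglik, tolerance = 1e-9)
})

test_that("AIC is -2 loglik + 2 x number of variance parameters", {
  hs <- make_halfsib_trial(nf = 30, no = 4, seed = 51)
  fit <- fit_univariate(hs$trial, "Y", model = "A")
  expect_equal(fit$aic, -2 * fit$loglik + 2 * 2)
  g <- glance(fit)
  expect_equal(g$AIC, fit$aic)
  expect_equal(g$n_varpar, 2L)
})

test_that("degenerate and absent responses fail loudly", {
  hs <- make_halfsib_trial(nf = 5, no = 2, seed = 61)
  tr <- hs$trial
  tr$data$Y <- 5
  expect_error(fit_univariate(tr, "Y"), "degenerate")
})

test_that("boundary variances are floored and flagged", {
  # pure-noise trait: the additive variance collapses towards its floor and
  # never goes negative
  hs <- make_halfsib_trial(nf = 150, no = 5, sigma2_A = 0, sigma2_e = 100,
                           seed = 71)
  fit <- fit_univariate(hs$trial, "Y", model = "A", max_iter = 80)
  h2_hat <- fit$theta[["sigma2_A"]] /
    (fit$theta[["sigma2_A"]] + fit$theta[["sigma2_e"]])
  expect_lt(h2_hat, 0.15)
  expect_gt(fit$theta[["sigma2_A"]], 0)
})

test_that("fixed-effect BLUEs match GLS at the estimated components", {
  hs <- make_halfsib_trial(nf = 30, no = 4, n_pop = 3, sigma2_pop = 200,
                           n_block = 3, sigma2_block = 50, seed = 81)
  fit <- fit_univariate(hs$trial, "Y", model = "B")
  d <- fit$design
  # dense GLS with V built from the estimated components
  A <- relationship_matrix(d$pedigree)
  idx <- match(d$rows$tree_id, d$pedigree$id)
  V <- fit$theta[["sigma2_A"]] * A[idx, idx] +
    fit$theta[["sigma2_e"]] * diag(d$n)
  Vi <- solve(V)
  XVX <- crossprod(d$X, Vi %*% d$X)
  beta_gls <- solve(XVX, crossprod(d$X, Vi %*% d$y))
  expect_equal(unname(fit$beta), as.numeric(beta_gls), tolerance = 1e-6)
  expect_equal(unname(fit$beta_cov), unname(solve(XVX)), tolerance = 1e-6)
})

test_that("BLUPs match the dense mixed-model prediction formula", {
  hs <- make_halfsib_trial(nf = 20, no = 3, seed = 91)
  fit <- fit_univariate(hs$trial, "Y", model = "A")
  d <- fit$design
  A <- relationship_matrix(d$pedigree)
  idx <- match(d$rows$tree_id, d$pedigree$id)
  V <- fit$theta[["sigma2_A"]] * A[idx, idx] +
    fit$theta[["sigma2_e"]] * diag(d$n)
  Vi <- solve(V)
  resid <- d$y - d$X %*% fit$beta
  u_dense <- fit$theta[["sigma2_A"]] * A[, idx] %*% (Vi %*% resid)
  expect_equal(unname(fit$u$additive), as.numeric(u_dense), tolerance = 1e-6)
})
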