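# Small in-code datasets shared across tests.

# balanced single-site half-sib trial: nf families x no offspring, one trait
make_halfsib_trial <- function(nf = 60, no = 5, sigma2_A = 300, sigma2_e = 600,
                               mu = 100, n_pop = 1, sigma2_pop = 0,
                               n_block = 1, sigma2_block = 0, seed = 1) {
  set.seed(seed)
  pops <- sprintf("P%d", seq_len(n_pop))
  mother <- sprintf("M%03d", seq_len(nf))
  mom_pop <- pops[rep_len(seq_len(n_pop), nf)]
  pop_eff <- stats::setNames(rnorm(n_pop, 0, sqrt(sigma2_pop)), pops)
  a_mom <- rnorm(nf, 0, sqrt(sigma2_A))
  off <- expand.grid(f = seq_len(nf), o = seq_len(no))
  g <- 0.5 * a_mom[off$f] + rnorm(nrow(off), 0, sqrt(0.75 * sigma2_A))
  blocks <- sprintf("B%02d", sample.int(n_block, nrow(off), replace = TRUE))
  blk_eff <- stats::setNames(rnorm(n_block, 0, sqrt(sigma2_block)),
                             sprintf("B%02d", seq_len(n_block)))
  y <- mu + pop_eff[mom_pop[off$f]] + blk_eff[blocks] + g +
    rnorm(nrow(off), 0, sqrt(sigma2_e))
  phen <- data.frame(
    tree_id = sprintf("T%04d", seq_len(nrow(off))),
    mother_id = mother[off$f],
    population = mom_pop[off$f],
    site = "S1", block = blocks, Y = as.numeric(y)
  )
  ped <- data.frame(individual = phen$tree_id, mother = phen$mother_id,
                    father = NA_character_)
  list(trial = trial_data(phen, ped), phen = phen,
       truth = list(sigma2_A = sigma2_A, sigma2_e = sigma2_e))
}

# random valid pedigree of n individuals (possibly inbred, both parents known
# for some) in topological order
make_random_pedigree <- function(n, p_known = 0.7, seed = 1) {
  set.seed(seed)
  id <- sprintf("I%04d", seq_len(n))
  mother <- father <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i > 2 && stats::runif(1) < p_known) {
      mother[i] <- id[sample.int(i - 1, 1)]
      if (stats::runif(1) < 0.6) {
        father[i] <- id[sample.int(i - 1, 1)]
        if (identical(father[i], mother[i])) father[i] <- NA_character_
      }
    }
  }
  data.frame(individual = id, mother = mother, father = father)
}

# dense REML log-likelihood for y = mu + fam + e (balanced half-sib family
# model), used as an independent oracle for the animal-model fit
family_model_loglik <- function(y, fam, s2f, s2w) {
  n <- length(y)
  Zf <- outer(fam, sort(unique(fam)), `==`) * 1
  V <- s2f * tcrossprod(Zf) + s2w * diag(n)
  X <- matrix(1, n, 1)
  Vi <- solve(V)
  XVX <- crossprod(X, Vi %*% X)
  b <- solve(XVX, crossprod(X, Vi %*% y))
  r <- y - X %*% b
  quad <- as.numeric(crossprod(r, Vi %*% r))
  -0.5 * (as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(XVX)$modulus) + quad +
            (n - 1) * log(2 * pi))
}
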