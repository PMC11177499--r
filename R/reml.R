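#' Fit an animal model by average-information REML
#'
#' Maximizes the restricted log-likelihood of the mixed model described by a
#' [build_design()] system. The engine works on the sparse mixed-model
#' equations: each likelihood evaluation is one sparse Cholesky factorization
#' of the coefficient matrix
#' \deqn{C = W' R^{-1} W + [0, G^{-1}]}
#' with \eqn{W = [X, Z]}, using the pedigree-derived sparse \eqn{A^{-1}}.
#' Updates are Newton steps on the average-information matrix
#' \eqn{AI_{ij} = \tfrac12 (Q_i P y)' P (Q_j P y)} (with
#' \eqn{Q_i = \partial V/\partial\theta_i}), where the score is obtained by
#' central finite differences of the exact restricted log-likelihood.
#' Steps that would decrease the log-likelihood, leave the parameter space
#' (a variance below its floor, a 2x2 covariance block losing positive
#' definiteness) are halved until they improve, so the fitted log-likelihood
#' trace is non-decreasing by construction.
#'
#' Variance components are floored at `1e-6` times the phenotypic variance of
#' the trait rather than being allowed to go negative; estimates ending on
#' the floor (or a correlation pinned at +-1) are flagged in `$boundary`.
#' The asymptotic covariance of the variance components is the inverse of the
#' average-information matrix at the optimum.
#'
#' @param design A `qg_design` from [build_design()].
#' @param start_values Optional named numeric vector of starting values for
#'   the variance parameters (defaults partition the phenotypic variance).
#' @param tol Convergence tolerance on the relative change in restricted
#'   log-likelihood (and on relative parameter updates).
#' @param max_iter Maximum number of AI iterations.
#' @param verbose Print the iteration trace.
#' @return An object of class `qg_fit` with elements `theta` (named variance
#'   parameters), `vc_covariance`, `beta`/`beta_cov` (fixed-effect solutions),
#'   `u` (BLUPs per random term), `loglik`, `aic` (`-2 loglik + 2 x` number of
#'   variance parameters), `converged`, `iterations`, `boundary` and the
#'   iteration `trace`.
#' @export
reml_fit <- function(design, start_values = NULL, tol = 1e-8, max_iter = 50L,
                     verbose = FALSE) {
  stopifnot(inherits(design, "qg_design"))
  info <- theta_info(design)
  npar <- nrow(info)
  floor_vec <- ifelse(info$kind == "var", 1e-6 * info$scale, -Inf)

  theta <- default_start(info)
  if (!is.null(start_values)) {
    common <- intersect(names(start_values), info$name)
    theta[match(common, info$name)] <- start_values[common]
  }
  theta <- project_feasible(theta, info, floor_vec)

  cache <- make_reml_cache(design)
  ev <- reml_eval(design, theta, cache)
  ll <- ev$loglik
  trace <- list(tibble::tibble(iter = 0L, loglik = ll, step = NA_real_))

  converged <- FALSE
  iterations <- 0L
  AI <- NULL
  for (iter in seq_len(max_iter)) {
    iterations <- iter
    g <- fd_score(design, theta, cache, info, floor_vec, ll)
    AI <- ai_matrix(design, theta, cache, ev, info)
    delta <- tryCatch(
      solve(AI + diag(1e-8 * max(abs(diag(AI))), npar), g),
      error = function(e) g / pmax(abs(diag(AI)), 1e-12)
    )
    # trust-region-style cap: no parameter moves by more than half its
    # current magnitude or a fifth of its phenotypic scale in one step
    cap <- pmax(0.5 * abs(theta), 0.2 * info$scale)
    fac <- min(1, cap / pmax(abs(delta), 1e-300))
    delta <- fac * delta
    step <- 1
    repeat {
      cand <- project_feasible(theta + step * delta, info, floor_vec)
      ok <- feasible(cand, info)
      ev_new <- if (ok) reml_eval(design, cand, cache) else NULL
      if (ok && is.finite(ev_new$loglik) && ev_new$loglik >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-10) break
    }
    if (step < 1e-10) {
      # no uphill AI step exists within machine precision: treat the current
      # point as the optimum if the projected gradient is negligible
      converged <- max(abs(projected_grad(g, theta, floor_vec))) <
        1e-3 * (1 + abs(ll))
      break
    }
    rel_ll <- abs(ev_new$loglik - ll) / (1 + abs(ll))
    rel_par <- max(abs(cand - theta) / (abs(theta) + 1e-3 * info$scale))
    if (verbose) {
      message(sprintf("iter %d loglik %.8f step %.3g", iter, ev_new$loglik, step))
    }
    theta <- cand
    ll <- ev_new$loglik
    ev <- ev_new
    trace <- c(trace, list(tibble::tibble(iter = iter, loglik = ll, step = step)))
    if (rel_ll < tol && rel_par < sqrt(tol)) {
      converged <- TRUE
      break
    }
  }
  trace <- dplyr::bind_rows(trace)

  boundary <- (info$kind == "var" & theta <= floor_vec * (1 + 1e-6))
  for (b in cov_blocks(info)) {
    v1 <- theta[b[1]]; cv <- theta[b[2]]; v2 <- theta[b[3]]
    if (abs(cv) >= (1 - 1e-4) * sqrt(v1 * v2)) boundary[b[2]] <- TRUE
  }
  names(boundary) <- info$name

  AI <- ai_matrix(design, theta, cache, ev, info)
  vc_cov <- tryCatch(solve(AI), error = function(e) {
    ev_ai <- eigen(AI, symmetric = TRUE)
    worst <- info$name[which.max(abs(ev_ai$vectors[, npar]))]
    stop("average-information matrix is singular; component '", worst,
         "' appears unidentifiable", call. = FALSE)
  })
  dimnames(vc_cov) <- list(info$name, info$name)

  sol <- ev$sol
  p <- design$p
  beta <- stats::setNames(as.numeric(sol[seq_len(p)]), colnames(design$X))
  u_all <- as.numeric(sol[-seq_len(p)])
  u <- list()
  for (ci in seq_along(design$components)) {
    comp <- design$components[[ci]]
    idx <- (design$comp_offsets[ci] + 1):design$comp_offsets[ci + 1]
    ui <- u_all[idx]
    if (comp$type == "cov2") {
      u[[comp$name]] <- matrix(ui, ncol = 2,
                               dimnames = list(comp$level_ids, comp$copy_names))
    } else {
      u[[comp$name]] <- stats::setNames(ui, comp$level_ids)
    }
  }
  beta_cov <- beta_covariance(ev, p)
  dimnames(beta_cov) <- list(names(beta), names(beta))

  structure(list(
    theta = stats::setNames(theta, info$name),
    vc_covariance = vc_cov,
    beta = beta, beta_cov = beta_cov, u = u,
    loglik = ll, aic = -2 * ll + 2 * npar,
    converged = converged, iterations = iterations,
    boundary = boundary, trace = trace,
    n = design$n, p = p, npar = npar,
    design = design
  ), class = "qg_fit")
}

theta_info <- function(design) {
  rows <- list()
  for (ci in seq_along(design$components)) {
    comp <- design$components[[ci]]
    np_c <- length(comp$par_names)
    rows[[length(rows) + 1]] <- tibble::tibble(
      name = comp$par_names, kind = comp$par_kind,
      scale = unname(comp$par_scale), comp = ci, pos = seq_len(np_c)
    )
  }
  r <- design$residual
  np_r <- length(r$par_names)
  rows[[length(rows) + 1]] <- tibble::tibble(
    name = r$par_names, kind = r$par_kind, scale = unname(r$par_scale),
    comp = 0L, pos = seq_len(np_r)
  )
  dplyr::bind_rows(rows)
}

default_start <- function(info) {
  # half the phenotypic variance per variance parameter; covariances start at
  # 0 so the first steps do not commit to a correlation sign
  ifelse(info$kind == "var", 0.5 * info$scale, 0)
}

# index triples (v1, cov, v2) of every 2x2 covariance block in theta
cov_blocks <- function(info) {
  out <- list()
  ci <- which(info$kind == "cov")
  for (i in ci) out[[length(out) + 1]] <- c(i - 1L, i, i + 1L)
  out
}

# variances are floored by projection; covariance blocks losing positive
# definiteness are handled by step-halving (feasible() below), so boundary
# correlations are approached from inside rather than jumped onto
project_feasible <- function(theta, info, floor_vec) {
  pmax(theta, floor_vec)
}

feasible <- function(theta, info) {
  if (any(!is.finite(theta))) return(FALSE)
  for (b in cov_blocks(info)) {
    if (theta[b[2]]^2 >= (1 - 1e-10) * theta[b[1]] * theta[b[3]]) return(FALSE)
  }
  all(theta[info$kind == "var"] > 0)
}

projected_grad <- function(g, theta, floor_vec) {
  at_floor <- theta <= floor_vec * (1 + 1e-6)
  ifelse(at_floor & g < 0, 0, g)
}

make_reml_cache <- function(design) {
  cache <- new.env(parent = emptyenv())
  Xs <- Matrix::Matrix(design$X, sparse = TRUE)
  cache$W <- cbind(Xs, design$Z)
  cache$Wt <- Matrix::t(cache$W)
  cache$y <- design$y
  cache$info <- theta_info(design)
  cache$chol <- NULL
  cache$Kchol <- lapply(design$components, function(comp) {
    Ksym <- Matrix::forceSymmetric(methods::as(comp$Kinv, "CsparseMatrix"))
    Matrix::Cholesky(Ksym, LDL = FALSE, perm = TRUE)
  })
  r <- design$residual
  if (r$type == "unstructured2") {
    n <- design$n
    half <- n / 2
    cache$partner <- ifelse(r$slot == 1L, seq_len(n) + half, seq_len(n) - half)
  }
  cache
}

# G^{-1} (sparse, block diagonal over components) and log|G|
assemble_Ginv <- function(design, theta, info) {
  blocks <- list()
  logdetG <- 0
  for (ci in seq_along(design$components)) {
    comp <- design$components[[ci]]
    th <- theta[info$comp == ci]
    if (comp$type == "scalar") {
      blocks[[ci]] <- comp$Kinv / th[1]
      logdetG <- logdetG + comp$q_levels * log(th[1]) + comp$logdetK
    } else {
      S <- matrix(c(th[1], th[2], th[2], th[3]), 2, 2)
      Sinv <- solve(S)
      blocks[[ci]] <- rbind(
        cbind(Sinv[1, 1] * comp$Kinv, Sinv[1, 2] * comp$Kinv),
        cbind(Sinv[2, 1] * comp$Kinv, Sinv[2, 2] * comp$Kinv)
      )
      logdetG <- logdetG + comp$q_levels * as.numeric(determinant(S)$modulus) +
        2 * comp$logdetK
    }
  }
  list(Ginv = Matrix::bdiag(blocks), logdetG = logdetG)
}

# R^{-1} (sparse) and log|R|
assemble_Rinv <- function(design, theta, info, cache) {
  r <- design$residual
  th <- theta[info$comp == 0L]
  n <- design$n
  if (r$type == "diag_groups") {
    w <- 1 / th[r$groups]
    list(Rinv = Matrix::Diagonal(n, x = w),
         logdetR = sum(log(th[r$groups])))
  } else {
    S <- matrix(c(th[1], th[2], th[2], th[3]), 2, 2)
    Sinv <- solve(S)
    half <- n / 2
    dg <- ifelse(r$slot == 1L, Sinv[1, 1], Sinv[2, 2])
    Rinv <- Matrix::sparseMatrix(
      i = c(seq_len(n), seq_len(n)),
      j = c(seq_len(n), cache$partner),
      x = c(dg, rep(Sinv[1, 2], n)),
      dims = c(n, n), symmetric = FALSE
    )
    list(Rinv = Matrix::forceSymmetric(Rinv),
         logdetR = half * as.numeric(determinant(S)$modulus))
  }
}

# One restricted log-likelihood evaluation: sparse Cholesky of the MME.
reml_eval <- function(design, theta, cache) {
  info <- cache$info
  G <- assemble_Ginv(design, theta, info)
  R <- assemble_Rinv(design, theta, info, cache)
  p <- design$p
  WtRi <- cache$Wt %*% R$Rinv
  C <- WtRi %*% cache$W
  Gfull <- Matrix::bdiag(Matrix::Matrix(0, p, p), G$Ginv)
  Csp <- methods::as(Matrix::forceSymmetric(C + Gfull), "CsparseMatrix")
  ch <- NULL
  if (!is.null(cache$chol)) {
    ch <- tryCatch(Matrix::.updateCHMfactor(cache$chol, Csp, mult = 0),
                   error = function(e) NULL)
  }
  if (is.null(ch)) {
    ch <- Matrix::Cholesky(Csp, LDL = FALSE, perm = TRUE)
  }
  cache$chol <- ch
  rhs <- WtRi %*% cache$y
  sol <- Matrix::solve(ch, rhs)
  yRy <- sum(cache$y * as.numeric(R$Rinv %*% cache$y))
  yPy <- yRy - sum(as.numeric(sol) * as.numeric(rhs))
  logdetC <- 2 * as.numeric(determinant(ch, sqrt = TRUE)$modulus)
  n <- design$n
  loglik <- -0.5 * (R$logdetR + G$logdetG + logdetC + yPy + (n - p) * log(2 * pi))
  list(loglik = as.numeric(unname(loglik)), sol = as.numeric(sol), yPy = yPy,
       ch = ch, Rinv = R$Rinv, WtRi = WtRi, dim = ncol(Csp))
}

# P v = R^{-1} v - R^{-1} W C^{-1} W' R^{-1} v
P_times <- function(v, ev, cache) {
  Rv <- as.numeric(ev$Rinv %*% v)
  t1 <- ev$WtRi %*% v
  as.numeric(Rv - ev$Rinv %*% (cache$W %*% Matrix::solve(ev$ch, t1)))
}

# f_k = (dV/dtheta_k) P y for every variance parameter
dV_times_py <- function(design, theta, info, cache, Py) {
  n <- design$n
  fs <- vector("list", nrow(info))
  Ztpy <- as.numeric(Matrix::t(design$Z) %*% Py)
  for (k in seq_len(nrow(info))) {
    ci <- info$comp[k]
    if (ci == 0L) {
      r <- design$residual
      if (r$type == "diag_groups") {
        fs[[k]] <- Py * (r$groups == info$pos[k])
      } else {
        pos <- info$pos[k]
        if (pos == 2L) {
          fs[[k]] <- Py[cache$partner]
        } else {
          sl <- if (pos == 1L) 1L else 2L
          fs[[k]] <- Py * (r$slot == sl)
        }
      }
    } else {
      comp <- design$components[[ci]]
      idx <- (design$comp_offsets[ci] + 1):design$comp_offsets[ci + 1]
      w <- Ztpy[idx]
      Kch <- cache$Kchol[[ci]]
      if (comp$type == "scalar") {
        kw <- as.numeric(Matrix::solve(Kch, w))
        out <- kw
      } else {
        q <- comp$q_levels
        w1 <- w[seq_len(q)]; w2 <- w[q + seq_len(q)]
        kw1 <- as.numeric(Matrix::solve(Kch, w1))
        kw2 <- as.numeric(Matrix::solve(Kch, w2))
        out <- switch(info$pos[k],
                      c(kw1, numeric(q)),        # d/d sigma2_1 : E11 x K
                      c(kw2, kw1),               # d/d sigma_12 : (E12+E21) x K
                      c(numeric(q), kw2))        # d/d sigma2_2 : E22 x K
      }
      full <- numeric(ncol(design$Z))
      full[idx] <- out
      fs[[k]] <- as.numeric(design$Z %*% full)
    }
  }
  fs
}

ai_matrix <- function(design, theta, cache, ev, info) {
  Py <- P_times(design$y, ev, cache)
  fs <- dV_times_py(design, theta, info, cache, Py)
  npar <- length(fs)
  Pf <- lapply(fs, P_times, ev = ev, cache = cache)
  AI <- matrix(0, npar, npar)
  for (i in seq_len(npar)) {
    for (j in i:npar) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(fs[[i]] * Pf[[j]])
    }
  }
  dimnames(AI) <- list(info$name, info$name)
  AI
}

# central finite-difference score of the restricted log-likelihood; falls
# back to a one-sided difference against a parameter floor or a PD boundary
fd_score <- function(design, theta, cache, info, floor_vec, ll0) {
  npar <- length(theta)
  g <- numeric(npar)
  for (k in seq_len(npar)) {
    h <- 1e-5 * max(abs(theta[k]), 1e-3 * info$scale[k])
    up <- theta; up[k] <- theta[k] + h
    dn <- theta; dn[k] <- theta[k] - h
    up_ok <- feasible(up, info)
    dn_ok <- feasible(dn, info) && dn[k] > floor_vec[k]
    if (up_ok && dn_ok) {
      g[k] <- (reml_eval(design, up, cache)$loglik -
               reml_eval(design, dn, cache)$loglik) / (2 * h)
    } else if (up_ok) {
      g[k] <- (reml_eval(design, up, cache)$loglik - ll0) / h
    } else if (dn_ok) {
      g[k] <- (ll0 - reml_eval(design, dn, cache)$loglik) / h
    } else {
      g[k] <- 0
    }
  }
  g
}

beta_covariance <- function(ev, p) {
  E <- Matrix::sparseMatrix(i = seq_len(p), j = seq_len(p), x = 1,
                            dims = c(ev$dim, p))
  as.matrix(Matrix::solve(ev$ch, E))[seq_len(p), , drop = FALSE]
}

#' @export
print.qg_fit <- function(x, ...) {
  cat("<qg_fit> animal-model REML fit\n")
  cat(sprintf("  n = %d observations, %d fixed-effect columns\n", x$n, x$p))
  cat(sprintf("  logLik = %.4f  AIC = %.4f  (%s in %d iterations)\n",
              x$loglik, x$aic,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  est <- tidy(x)
  cat("  variance parameters:\n")
  for (i in seq_len(nrow(est))) {
    cat(sprintf("    %-22s %12.5g (SE %.4g)%s\n", est$term[i], est$estimate[i],
                est$std.error[i], if (est$boundary[i]) " [boundary]" else ""))
  }
  invisible(x)
}
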