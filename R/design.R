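#' Build the mixed-model design system for a model specification
#'
#' Translates a trial dataset plus a [model_spec()] into the matrices the REML
#' engine consumes: the full-rank fixed design `X` (treatment coding,
#' reference level = first by lexical sort, aliased columns dropped with later
#' terms dropped first), the sparse incidence `Z` mapping observations to
#' pedigree individuals (all pedigree members get an equation, so
#' unphenotyped relatives receive breeding values), and the covariance
#' templates of every random term and of the residual.
#'
#' Rows with a missing response are dropped (for bivariate models, only trees
#' with both traits observed are kept, so the 2x2 residual covariance is
#' estimated on jointly observed rows).
#'
#' @param trial A [trial_data()] object (or a list with elements `data` and
#'   `pedigree`).
#' @param spec A [model_spec()].
#' @param predict_ids Pedigree ids to retain in the equations even when
#'   unphenotyped (beyond ancestors of the phenotyped trees), so they receive
#'   breeding values — used by cross-validation for the held-out trees.
#' @return An object of class `qg_design` (a list of design matrices,
#'   covariance templates and parameter metadata).
#' @export
build_design <- function(trial, spec, predict_ids = NULL) {
  stopifnot(inherits(spec, "qg_model_spec"))
  data <- trial$data
  ped <- trial$pedigree
  if (!inherits(ped, "qg_pedigree")) ped <- build_pedigree(ped)

  responses <- spec$response
  missing_tr <- setdiff(responses, names(data))
  if (length(missing_tr) > 0) {
    stop("trait(s) not present in the data: ", paste(missing_tr, collapse = ", "),
         call. = FALSE)
  }
  bivariate <- length(responses) == 2

  keep <- if (bivariate) {
    stats::complete.cases(data[responses])
  } else {
    !is.na(data[[responses]])
  }
  data <- data[keep, , drop = FALSE]
  if (nrow(data) == 0) stop("no observations left for response ", responses[1],
                            call. = FALSE)
  for (tr in responses) {
    if (var(data[[tr]]) <= .Machine$double.eps) {
      stop("response '", tr, "' is degenerate (zero variance)", call. = FALSE)
    }
  }
  if (any(duplicated(data$tree_id))) {
    stop("duplicated tree_id among observed rows", call. = FALSE)
  }

  ped <- prune_pedigree(ped, c(data$tree_id,
                               intersect(predict_ids, ped$id)))
  if (anyNA(match(data$tree_id, ped$id))) {
    stop("phenotyped tree(s) absent from the pedigree", call. = FALSE)
  }

  fx <- build_fixed_matrix(data, spec$fixed)

  n_tree <- nrow(data)
  sites <- sort(unique(as.character(data$site)))
  site_idx <- match(as.character(data$site), sites)
  nped <- nrow(ped)
  tree_idx <- match(data$tree_id, ped$id)
  Ainv <- relationship_inverse(ped)
  logdetA <- attr(Ainv, "logdet")

  if (spec$genetic == "cov2_sites" && length(sites) != 2) {
    stop("a cross-site (type-B) model needs exactly 2 sites, got ",
         length(sites), call. = FALSE)
  }
  if (spec$genetic == "cov2_sites") {
    fam_per_site <- tapply(data$mother_id, site_idx, function(m) dplyr::n_distinct(m))
    if (any(fam_per_site < 2)) {
      stop("site with fewer than 2 families: additive (co)variance across sites ",
           "is not identifiable", call. = FALSE)
    }
  }

  # observation rows: bivariate models stack trait 1 rows then trait 2 rows
  if (bivariate) {
    n <- 2L * n_tree
    y <- c(data[[responses[1]]], data[[responses[2]]])
    X <- rbind(
      cbind(fx$X, matrix(0, n_tree, ncol(fx$X))),
      cbind(matrix(0, n_tree, ncol(fx$X)), fx$X)
    )
    colnames(X) <- c(paste0(responses[1], ":", colnames(fx$X)),
                     paste0(responses[2], ":", colnames(fx$X)))
    assign <- rep(fx$assign, 2)
    slot <- rep(1:2, each = n_tree)
    row_site <- rep(site_idx, 2)
    row_tree <- rep(tree_idx, 2)
  } else {
    n <- n_tree
    y <- data[[responses]]
    X <- fx$X
    assign <- fx$assign
    slot <- rep(1L, n)
    row_site <- site_idx
    row_tree <- tree_idx
  }

  # variance scale used for floors, starting values and finite-difference steps
  y_scale <- vapply(responses, function(tr) var(data[[tr]]), numeric(1))

  components <- list()
  Zs <- list()
  for (term in spec$random) {
    if (term == "additive") {
      if (spec$genetic == "single") {
        comp <- list(name = "additive", type = "scalar", copies = 1L,
                     q_levels = nped, Kinv = Ainv, logdetK = logdetA,
                     par_names = "sigma2_A", par_kind = "var",
                     par_scale = y_scale[1], level_ids = ped$id)
        Zc <- Matrix::sparseMatrix(i = seq_len(n), j = row_tree, x = 1,
                                   dims = c(n, nped))
      } else {
        copy_of <- if (spec$genetic == "cov2_traits") slot else row_site
        copy_names <- if (spec$genetic == "cov2_traits") responses else sites
        sc <- if (spec$genetic == "cov2_traits") y_scale else rep(y_scale[1], 2)
        comp <- list(name = "additive", type = "cov2", copies = 2L,
                     q_levels = nped, Kinv = Ainv, logdetK = logdetA,
                     copy_names = copy_names,
                     par_names = c(paste0("sigma2_A.", copy_names[1]),
                                   "sigma_A12",
                                   paste0("sigma2_A.", copy_names[2])),
                     par_kind = c("var", "cov", "var"),
                     par_scale = c(sc[1], sqrt(sc[1] * sc[2]), sc[2]),
                     level_ids = ped$id)
        Zc <- Matrix::sparseMatrix(i = seq_len(n),
                                   j = (copy_of - 1L) * nped + row_tree,
                                   x = 1, dims = c(n, 2L * nped))
      }
    } else if (term == "site_additive") {
      ns <- length(sites)
      comp <- list(name = "site_additive", type = "scalar", copies = 1L,
                   q_levels = ns * nped,
                   Kinv = Matrix::bdiag(rep(list(Ainv), ns)),
                   logdetK = ns * logdetA,
                   par_names = "sigma2_SG", par_kind = "var",
                   par_scale = y_scale[1],
                   level_ids = paste(rep(sites, each = nped), ped$id, sep = ":"))
      Zc <- Matrix::sparseMatrix(i = seq_len(n),
                                 j = (row_site - 1L) * nped + row_tree,
                                 x = 1, dims = c(n, ns * nped))
    } else if (term == "population") {
      pops <- sort(unique(as.character(data$population)))
      if (length(pops) < 2) {
        stop("random population term needs >= 2 populations", call. = FALSE)
      }
      comp <- list(name = "population", type = "scalar", copies = 1L,
                   q_levels = length(pops),
                   Kinv = Matrix::Diagonal(length(pops)), logdetK = 0,
                   par_names = "sigma2_G", par_kind = "var",
                   par_scale = y_scale[1], level_ids = pops)
      pop_idx <- match(as.character(data$population), pops)
      Zc <- Matrix::sparseMatrix(i = seq_len(n),
                                 j = rep(pop_idx, length.out = n),
                                 x = 1, dims = c(n, length(pops)))
    } else {
      stop("unknown random term: ", term, call. = FALSE)
    }
    components <- c(components, list(comp))
    Zs <- c(Zs, list(Zc))
  }
  if (length(components) == 0) stop("at least one random term is required",
                                    call. = FALSE)
  Z <- do.call(cbind, Zs)
  # dimension of each component's u block: q_levels for scalar structures
  # (site_additive already folds its site copies into q_levels), 2*q_levels
  # for a 2x2 covariance structure
  comp_dims <- vapply(components, function(c)
    (if (c$type == "cov2") 2L else 1L) * c$q_levels, numeric(1))
  comp_offsets <- c(0, cumsum(comp_dims))

  # residual structure
  if (spec$residual == "homogeneous") {
    resid <- list(type = "diag_groups", groups = rep(1L, n),
                  group_names = "sigma2_e",
                  par_names = "sigma2_e", par_kind = "var",
                  par_scale = y_scale[1])
  } else if (spec$residual == "by_site") {
    resid <- list(type = "diag_groups", groups = row_site,
                  group_names = paste0("sigma2_e.", sites),
                  par_names = paste0("sigma2_e.", sites), par_kind = "var",
                  par_scale = rep(y_scale[1], length(sites)))
  } else {
    resid <- list(type = "unstructured2", slot = slot,
                  pair_id = rep(seq_len(n_tree), 2),
                  par_names = c(paste0("sigma2_e.", responses[1]), "sigma_e12",
                                paste0("sigma2_e.", responses[2])),
                  par_kind = c("var", "cov", "var"),
                  par_scale = c(y_scale[1], sqrt(prod(y_scale)), y_scale[2]))
  }

  structure(list(
    y = y, X = X, assign = assign, dropped = fx$dropped, terms = fx$terms,
    Z = Z, components = components, comp_offsets = comp_offsets,
    residual = resid, n = n, p = ncol(X), responses = responses,
    spec = spec, sites = sites,
    rows = tibble::tibble(
      tree_id = rep(data$tree_id, length.out = n),
      site = rep(as.character(data$site), length.out = n),
      population = rep(as.character(data$population), length.out = n),
      trait = responses[slot],
      y = y
    ),
    tree_population = stats::setNames(as.character(data$population), data$tree_id),
    pedigree = ped
  ), class = "qg_design")
}

# Treatment-coded fixed design with greedy rank filtering: candidate columns
# are generated term by term in the order given, and a column is kept only if
# it increases the rank, so aliased columns of later terms are dropped first.
build_fixed_matrix <- function(data, fixed) {
  n <- nrow(data)
  cand <- list(`(Intercept)` = rep(1, n))
  cand_term <- "intercept"

  dummy_cols <- function(f, prefix) {
    lev <- sort(unique(as.character(f)))
    out <- list()
    for (l in lev[-1]) out[[paste0(prefix, l)]] <- as.numeric(f == l)
    out
  }
  for (term in setdiff(fixed, "intercept")) {
    if (term == "population") {
      cols <- dummy_cols(data$population, "population")
    } else if (term == "site") {
      cols <- dummy_cols(data$site, "site")
    } else if (term == "block") {
      cols <- list()
      for (s in sort(unique(as.character(data$site)))) {
        in_s <- as.character(data$site) == s
        lev <- sort(unique(as.character(data$block[in_s])))
        for (l in lev[-1]) {
          cols[[paste0("site", s, ":block", l)]] <-
            as.numeric(in_s & as.character(data$block) == l)
        }
      }
    } else if (term == "population_site") {
      cols <- list()
      pops <- sort(unique(as.character(data$population)))
      sts <- sort(unique(as.character(data$site)))
      for (p in pops[-1]) for (s in sts[-1]) {
        cols[[paste0("population", p, ":site", s)]] <-
          as.numeric(data$population == p & data$site == s)
      }
    } else {
      stop("unknown fixed term: ", term, call. = FALSE)
    }
    cand <- c(cand, cols)
    cand_term <- c(cand_term, rep(term, length(cols)))
  }

  Xc <- do.call(cbind, cand)
  keep <- logical(ncol(Xc))
  dropped <- character(0)
  cur <- matrix(numeric(0), n, 0)
  rank <- 0L
  for (j in seq_len(ncol(Xc))) {
    trial_m <- cbind(cur, Xc[, j])
    r <- qr(trial_m)$rank
    if (r > rank) {
      keep[j] <- TRUE
      cur <- trial_m
      rank <- r
    } else {
      dropped <- c(dropped, colnames(Xc)[j])
    }
  }
  # a term whose candidate columns were all aliased is confounded
  for (term in unique(cand_term)) {
    in_term <- cand_term == term
    if (any(in_term) && sum(in_term) > 0 && !any(keep[in_term]) &&
        term %in% c("population", "site")) {
      stop("fixed term '", term, "' is completely confounded; aliased columns: ",
           paste(colnames(Xc)[in_term], collapse = ", "), call. = FALSE)
    }
  }
  list(X = Xc[, keep, drop = FALSE], assign = cand_term[keep],
       dropped = dropped, terms = unique(cand_term[keep]))
}

# Keep only `ids` and their ancestors.
prune_pedigree <- function(pedigree, ids) {
  keep <- logical(nrow(pedigree))
  keep[match(unique(ids), pedigree$id)] <- TRUE
  mi <- attr(pedigree, "mother_idx")
  fi <- attr(pedigree, "father_idx")
  for (i in rev(seq_len(nrow(pedigree)))) {
    if (keep[i]) {
      if (!is.na(mi[i])) keep[mi[i]] <- TRUE
      if (!is.na(fi[i])) keep[fi[i]] <- TRUE
    }
  }
  if (all(keep)) return(pedigree)
  build_pedigree(data.frame(individual = pedigree$id[keep],
                            mother = pedigree$mother[keep],
                            father = pedigree$father[keep]))
}
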