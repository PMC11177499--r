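#' Assign trees to cross-validation folds
#'
#' Random folds of approximately equal size (sizes differ by at most one),
#' deterministic given the seed. Folding is by individual tree; family-level
#' folding (all offspring of a mother in the same fold) is available via
#' `by_family`, which prevents half-sib information from linking training
#' and test sets.
#'
#' @param tree_ids Character vector of phenotyped tree ids (or, with
#'   `by_family`, a two-column data frame `tree_id`, `mother_id`).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @param by_family Assign whole half-sib families to folds.
#' @return Tibble `tree_id`, `fold` with attribute `seed`.
#' @export
kfold_split <- function(tree_ids, k = 5, seed = 1L, by_family = FALSE) {
  stopifnot(k >= 2)
  if (by_family) {
    stopifnot(is.data.frame(tree_ids),
              all(c("tree_id", "mother_id") %in% names(tree_ids)))
    fams <- unique(tree_ids$mother_id)
    if (length(fams) < k) stop("fewer families than folds", call. = FALSE)
    withr_seed(seed)
    fam_fold <- sample(rep_len(seq_len(k), length(fams)))
    out <- tibble::tibble(
      tree_id = as.character(tree_ids$tree_id),
      fold = fam_fold[match(tree_ids$mother_id, fams)]
    )
  } else {
    ids <- if (is.data.frame(tree_ids)) as.character(tree_ids$tree_id) else
      as.character(tree_ids)
    n <- length(ids)
    if (n < k) stop("fewer trees (", n, ") than folds (", k, ")", call. = FALSE)
    withr_seed(seed)
    out <- tibble::tibble(tree_id = ids, fold = sample(rep_len(seq_len(k), n)))
  }
  attr(out, "seed") <- as.integer(seed)
  out
}

# local seed without disturbing the caller's RNG stream
withr_seed <- function(seed) {
  set.seed(as.integer(seed))
  invisible(NULL)
}

#' k-fold cross-validation of an evaluation model
#'
#' For each fold, the model is refitted on the remaining folds (the test
#' trees' phenotypes are withheld, but the trees stay in the pedigree), the
#' test trees' breeding values are predicted through their pedigree
#' connections, and the Pearson correlation between predicted EBVs and the
#' withheld phenotypes is recorded. Predictive ability (PA) is the mean of
#' the fold correlations; its standard error is `sd(correlations)/sqrt(k)`.
#' Prediction accuracy is `ACC = PA / mean(sqrt(h2_fold))`, the PA scaled by
#' the average square root of the heritabilities estimated in each training
#' fit.
#'
#' A fold whose test trees have no phenotyped relatives in training (the
#' correlation is undefined) is excluded with a warning.
#'
#' @param trial A [trial_data()] object.
#' @param trait Trait to evaluate.
#' @param site Site to evaluate (per-site CV is the default reporting unit;
#'   `NULL` uses all sites jointly).
#' @param model `"A"` or `"B"` (population fixed effect excluded/included).
#' @param k Number of folds.
#' @param seed Seed for the fold assignment.
#' @param folds Optional precomputed [kfold_split()] assignment (overrides
#'   `k`/`seed`); required to compare models on identical folds.
#' @param ... Passed to [reml_fit()].
#' @return A `qg_cv` object: tibble of per-fold results with attributes and
#'   columns summarised by [glance()]; fields `trait`, `model_variant`, `pa`,
#'   `pa_se`, `acc`.
#' @export
run_cv <- function(trial, trait, site = NULL, model = c("B", "A"), k = 5,
                   seed = 1L, folds = NULL, ...) {
  model <- match.arg(model)
  sub <- subset_site(trial, site)
  phen <- sub$data[!is.na(sub$data[[trait]]), , drop = FALSE]
  if (is.null(folds)) {
    folds <- kfold_split(phen$tree_id, k = k, seed = seed)
  }
  fold_seed <- attr(folds, "seed")
  folds <- folds[folds$tree_id %in% phen$tree_id, , drop = FALSE]
  attr(folds, "seed") <- fold_seed
  if (!setequal(folds$tree_id, phen$tree_id)) {
    stop("fold assignment does not cover the phenotyped trees", call. = FALSE)
  }
  kk <- sort(unique(folds$fold))

  per_fold <- purrr::map_dfr(kk, function(f) {
    test_ids <- folds$tree_id[folds$fold == f]
    train <- sub
    hold <- train$data$tree_id %in% test_ids
    train$data[[trait]][hold] <- NA_real_
    fit <- fit_univariate(train, trait, site = NULL, model = model,
                          predict_ids = test_ids, ...)
    h2f <- if ("sigma2_e" %in% names(fit$theta)) {
      heritability(fit)$h2
    } else {
      # joint multi-site fit: average the per-site heritabilities
      mean(vapply(sort(unique(sub$data$site)),
                  function(s) heritability(fit, site = s)$h2, numeric(1)))
    }
    ebv <- compute_ebv(fit, model_variant = model)
    pred <- ebv$ebv[match(test_ids, ebv$tree_id)]
    obs <- phen[[trait]][match(test_ids, phen$tree_id)]
    ok <- !is.na(pred) & !is.na(obs)
    r <- if (sum(ok) >= 3 && sd(pred[ok]) > 0 && sd(obs[ok]) > 0) {
      cor(pred[ok], obs[ok])
    } else NA_real_
    tibble::tibble(fold = f, n_test = sum(ok), correlation = r, h2 = h2f,
                   converged = fit$converged)
  })

  bad <- is.na(per_fold$correlation)
  if (any(bad)) {
    warning(sum(bad), " fold(s) had an undefined EBV-phenotype correlation ",
            "and were excluded", call. = FALSE)
  }
  use <- per_fold[!bad, , drop = FALSE]
  pa <- mean(use$correlation)
  pa_se <- sd(use$correlation) / sqrt(nrow(use))
  acc <- pa / mean(sqrt(use$h2))

  structure(list(
    per_fold = per_fold, trait = trait, model_variant = model,
    site = site %||% "all", k = length(kk), seed = attr(folds, "seed"),
    folds = folds, pa = pa, pa_se = pa_se, acc = acc
  ), class = "qg_cv")
}

#' @export
print.qg_cv <- function(x, ...) {
  cat(sprintf("<qg_cv> trait %s, model-%s, site %s (%d folds)\n",
              x$trait, x$model_variant, x$site, x$k))
  cat(sprintf("  PA = %.3f (SE %.3f)   ACC = %.3f\n", x$pa, x$pa_se, x$acc))
  invisible(x)
}

#' Compare the cross-validated performance of two evaluation models
#'
#' Reports the change in predictive ability and prediction accuracy between
#' two [run_cv()] results on identical folds, and the relative ACC
#' improvement `100 (ACC_B - ACC_A) / ACC_B` (the improvement expressed as a
#' share of the better model's accuracy).
#'
#' @param cv_a,cv_b `qg_cv` results for the two model variants on the same
#'   trait and fold assignment.
#' @return One-row tibble: `trait`, `site`, `pa_a`, `pa_b`, `acc_a`, `acc_b`,
#'   `delta_pa`, `delta_acc`, `acc_improvement_pct`.
#' @export
compare_models <- function(cv_a, cv_b) {
  stopifnot(inherits(cv_a, "qg_cv"), inherits(cv_b, "qg_cv"))
  if (cv_a$trait != cv_b$trait) stop("CV reports are for different traits",
                                     call. = FALSE)
  fa <- dplyr::arrange(cv_a$folds, .data$tree_id)
  fb <- dplyr::arrange(cv_b$folds, .data$tree_id)
  if (!identical(fa$tree_id, fb$tree_id) || !identical(fa$fold, fb$fold)) {
    stop("CV reports use different fold assignments; rerun with shared folds",
         call. = FALSE)
  }
  tibble::tibble(
    trait = cv_a$trait, site = cv_a$site,
    pa_a = cv_a$pa, pa_b = cv_b$pa,
    acc_a = cv_a$acc, acc_b = cv_b$acc,
    delta_pa = cv_b$pa - cv_a$pa,
    delta_acc = cv_b$acc - cv_a$acc,
    acc_improvement_pct = acc_improvement_pct(cv_a$acc, cv_b$acc)
  )
}

#' @describeIn compare_models Arithmetic helper:
#'   `100 (acc_b - acc_a) / acc_b`.
#' @param acc_a,acc_b Accuracy values.
#' @export
acc_improvement_pct <- function(acc_a, acc_b) {
  100 * (acc_b - acc_a) / acc_b
}
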