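#' Build a validated, topologically ordered pedigree
#'
#' Assembles a pedigree from individual/mother/father records, adding implicit
#' founder entries for parents that are referenced but never declared, and
#' reordering so that every parent precedes its offspring. Open-pollinated
#' progeny are recorded with an unknown father; unknown parents are encoded as
#' `NA`, `""` or `"0"` in the input.
#'
#' @param records A data frame with columns `individual`, `mother` and
#'   (optionally) `father`. Additional columns are ignored.
#' @return An object of class `qg_pedigree`: a tibble with character columns
#'   `id`, `mother`, `father` (`NA` = unknown) in parents-before-offspring
#'   order, integer attribute columns `mother_idx`/`father_idx`, and the
#'   per-individual inbreeding coefficient `inbreeding`.
#' @examples
#' ped <- build_pedigree(data.frame(
#'   individual = c("o1", "o2", "o3"),
#'   mother = c("m1", "m1", "m2")
#' ))
#' ped$id # founders m1, m2 added implicitly and ordered first
#' @export
build_pedigree <- function(records) {
  stopifnot(is.data.frame(records))
  if (!all(c("individual", "mother") %in% names(records))) {
    stop("pedigree records need at least columns 'individual' and 'mother'",
         call. = FALSE)
  }
  if (!"father" %in% names(records)) records$father <- NA_character_
  rec <- tibble::tibble(
    id     = as.character(records$individual),
    mother = normalize_parent(records$mother),
    father = normalize_parent(records$father)
  )
  if (anyNA(rec$id) || any(rec$id == "")) {
    stop("pedigree contains an empty individual id", call. = FALSE)
  }

  dup <- rec |> dplyr::distinct() |> dplyr::count(.data$id) |> dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("individual(s) declared twice with conflicting parents: ",
         paste(dup$id, collapse = ", "), call. = FALSE)
  }
  rec <- dplyr::distinct(rec)

  declared <- rec$id
  referenced <- unique(stats::na.omit(c(rec$mother, rec$father)))
  founders <- setdiff(referenced, declared)
  if (length(founders) > 0) {
    rec <- dplyr::bind_rows(
      tibble::tibble(id = founders, mother = NA_character_, father = NA_character_),
      rec
    )
  }

  ord <- pedigree_toposort(rec)
  rec <- rec[ord, ]

  idx <- function(p) {
    out <- match(p, rec$id)
    out[is.na(p)] <- NA_integer_
    out
  }
  mi <- idx(rec$mother)
  fi <- idx(rec$father)
  ped <- tibble::new_tibble(
    list(id = rec$id, mother = rec$mother, father = rec$father),
    nrow = nrow(rec), class = "qg_pedigree"
  )
  attr(ped, "mother_idx") <- mi
  attr(ped, "father_idx") <- fi
  ped$inbreeding <- pedigree_inbreeding(mi, fi)
  ped
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "" | x == "0")] <- NA_character_
  x
}

# Kahn's algorithm; errors on cycles (an individual being its own ancestor).
pedigree_toposort <- function(rec) {
  n <- nrow(rec)
  pos <- stats::setNames(seq_len(n), rec$id)
  parents <- cbind(unname(pos[rec$mother]), unname(pos[rec$father]))
  indeg <- rowSums(!is.na(parents))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in parents[i, ]) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0)
  out <- integer(0)
  while (length(queue) > 0) {
    i <- queue[1]; queue <- queue[-1]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1
      if (indeg[ch] == 0) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    stop("pedigree contains a cycle involving: ",
         paste(rec$id[setdiff(seq_len(n), out)], collapse = ", "), call. = FALSE)
  }
  out
}

# Meuwissen & Luo recursion on the ordered pedigree. d_i is the Mendelian
# sampling variance 0.5 - 0.25(F_s + F_d), with an unknown parent entering as
# F = -1 (so both unknown gives d = 1); F_i = sum_j L_ij^2 d_j - 1.
pedigree_inbreeding <- function(mother_idx, father_idx) {
  n <- length(mother_idx)
  f <- numeric(n)
  d <- numeric(n)
  for (i in seq_len(n)) {
    s <- father_idx[i]; m <- mother_idx[i]
    fs <- if (is.na(s)) -1 else f[s]
    fm <- if (is.na(m)) -1 else f[m]
    d[i] <- 0.5 - 0.25 * (fs + fm)
    if (is.na(s) && is.na(m)) {
      f[i] <- 0
      next
    }
    L <- numeric(i)
    L[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      aii <- aii + L[j]^2 * d[j]
      for (p in c(mother_idx[j], father_idx[j])) {
        if (!is.na(p)) L[p] <- L[p] + 0.5 * L[j]
      }
    }
    f[i] <- aii - 1
  }
  f
}

#' Dense numerator relationship matrix
#'
#' Computes the additive (numerator) relationship matrix A by the tabular
#' method: `a_ii = 1 + 0.5 a(mother, father)` and
#' `a_ij = 0.5 (a(j, mother_i) + a(j, father_i))`, an unknown parent
#' contributing zero. Quadratic in pedigree size; intended for pedigrees up to
#' a few thousand individuals. Larger models only ever need the sparse inverse
#' from [relationship_inverse()].
#'
#' @param pedigree A [build_pedigree()] object.
#' @return A dense symmetric matrix with individual ids as dimnames.
#' @examples
#' ped <- build_pedigree(data.frame(individual = c("a", "b"), mother = c("m", "m")))
#' relationship_matrix(ped)["a", "b"] # half-sibs: 0.25
#' @export
relationship_matrix <- function(pedigree) {
  stopifnot(inherits(pedigree, "qg_pedigree"))
  mi <- attr(pedigree, "mother_idx")
  fi <- attr(pedigree, "father_idx")
  n <- nrow(pedigree)
  A <- matrix(0, n, n, dimnames = list(pedigree$id, pedigree$id))
  for (i in seq_len(n)) {
    m <- mi[i]; s <- fi[i]
    ams <- if (!is.na(m) && !is.na(s)) A[m, s] else 0
    A[i, i] <- 1 + 0.5 * ams
    if (i > 1) {
      j <- seq_len(i - 1)
      aij <- 0.5 * ((if (!is.na(m)) A[j, m] else 0) + (if (!is.na(s)) A[j, s] else 0))
      A[i, j] <- aij
      A[j, i] <- aij
    }
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds A-inverse directly from the pedigree by Henderson's rules, using
#' exact Mendelian-sampling variances from the inbreeding coefficients of the
#' parents, so inbred pedigrees are handled exactly. Each individual
#' contributes at most 9 nonzeros (its parent trio).
#'
#' @inheritParams relationship_matrix
#' @return A symmetric sparse matrix (`Matrix::dsCMatrix`) with attribute
#'   `"logdet"` holding log det(A) (the sum of log Mendelian-sampling
#'   variances), used by the REML engine.
#' @examples
#' ped <- build_pedigree(data.frame(individual = "o", mother = "m"))
#' round(as.matrix(relationship_inverse(ped)), 3)
#' @export
relationship_inverse <- function(pedigree) {
  stopifnot(inherits(pedigree, "qg_pedigree"))
  mi <- attr(pedigree, "mother_idx")
  fi <- attr(pedigree, "father_idx")
  f <- pedigree$inbreeding
  n <- nrow(pedigree)

  fs <- ifelse(is.na(fi), -1, f[ifelse(is.na(fi), 1L, fi)])
  fm <- ifelse(is.na(mi), -1, f[ifelse(is.na(mi), 1L, mi)])
  d <- 0.5 - 0.25 * (fs + fm)
  alpha <- 1 / d

  ii <- jj <- integer(0); xx <- numeric(0)
  push <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (i in seq_len(n)) {
    a <- alpha[i]
    par <- c(mi[i], fi[i])
    par <- par[!is.na(par)]
    push(i, i, a)
    for (p in par) {
      push(i, p, -a / 2); push(p, i, -a / 2)
    }
    if (length(par) > 0) {
      for (p in par) for (q in par) push(p, q, a / 4)
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(pedigree$id, pedigree$id))
  Ainv <- Matrix::forceSymmetric(Ainv)
  attr(Ainv, "logdet") <- sum(log(d))
  Ainv
}

#' Write a symmetric matrix as coordinate triplets
#'
#' Serializes a (sparse or dense) relationship matrix to delimited text with
#' columns `i`, `j`, `value` (1-based indices, upper triangle including the
#' diagonal), preceded by a header. Companion ids are written in index order
#' as a `# id:` comment line by row index.
#'
#' @param mat Matrix to export (e.g. from [relationship_matrix()] or
#'   [relationship_inverse()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_triplets <- function(mat, path) {
  sm <- methods::as(methods::as(Matrix::Matrix(mat, sparse = TRUE), "generalMatrix"), "TsparseMatrix")
  keep <- sm@i <= sm@j
  tb <- tibble::tibble(i = sm@i[keep] + 1L, j = sm@j[keep] + 1L, value = sm@x[keep]) |>
    dplyr::arrange(.data$i, .data$j)
  readr::write_tsv(tb, path)
  invisible(path)
}
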