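test_that("pedigree assembly adds founders and orders parents first", {
  ped <- build_pedigree(data.frame(
    individual = c("o1", "o2", "o3", "o4"),
    mother = c("m1", "m1", "m2", "m2")
  ))
  expect_equal(nrow(ped), 6)
  expect_true(all(match(c("m1", "m2"), ped$id) <
                    match(c("o1", "o3"), ped$id)))

  # offspring listed before its mother gets reordered
  ped2 <- build_pedigree(data.frame(
    individual = c("kid", "mom"), mother = c("mom", NA)
  ))
  expect_equal(ped2$id, c("mom", "kid"))
})

test_that("cycles and conflicting duplicate declarations are hard errors", {
  expect_error(build_pedigree(data.frame(
    individual = c("a", "b"), mother = c("b", "a")
  )), "cycle")
  expect_error(build_pedigree(data.frame(
    individual = c("a", "a"), mother = c("m1", "m2")
  )), "conflicting")
})

test_that("random pedigrees are topologically ordered", {
  for (s in 1:5) {
    rec <- make_random_pedigree(60, seed = s)
    ped <- build_pedigree(rec[sample.int(nrow(rec)), ])
    pos <- stats::setNames(seq_len(nrow(ped)), ped$id)
    parent_after <- mapply(function(i, p) !is.na(p) && pos[p] > pos[i],
                           ped$id, ped$mother)
    expect_false(any(parent_after))
  }
})

test_that("relationship matrix has textbook values", {
  # founders only -> identity
  f <- build_pedigree(data.frame(individual = c("x", "y"),
                                 mother = NA_character_))
  expect_equal(relationship_matrix(f), diag(2) * 1,
               ignore_attr = TRUE)
  # half-sibs share 0.25, mother-offspring 0.5, diagonals 1 (non-inbred)
  hs <- build_pedigree(data.frame(individual = c("a", "b"),
                                  mother = c("m", "m")))
  A <- relationship_matrix(hs)
  expect_equal(A["a", "b"], 0.25)
  expect_equal(A["m", "a"], 0.5)
  expect_equal(unname(diag(A)), rep(1, 3))
})

test_that("half-sib family blocks are exactly 0.25 off-diagonal", {
  rec <- data.frame(individual = sprintf("o%d", 1:8),
                    mother = rep(c("m1", "m2"), each = 4))
  A <- relationship_matrix(build_pedigree(rec))
  fam1 <- sprintf("o%d", 1:4)
  off <- A[fam1, fam1][upper.tri(diag(4))]
  expect_equal(unname(off), rep(0.25, 6))
  expect_equal(unname(A[sprintf("o%d", 1:4), sprintf("o%d", 5:8)]),
               matrix(0, 4, 4))
})

test_that("sparse A-inverse matches closed forms and dense inversion", {
  # one known parent: textbook 2x2 inverse
  mo <- build_pedigree(data.frame(individual = "o", mother = "m"))
  Ai <- as.matrix(relationship_inverse(mo))
  expect_equal(Ai, matrix(c(4, -2, -2, 4) / 3, 2, 2), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(Ai, solve(matrix(c(1, .5, .5, 1), 2)), ignore_attr = TRUE)

  # random pedigrees (inbreeding possible): A^-1 A = I and Cholesky of A works
  for (s in 1:4) {
    n <- c(80, 150, 220, 300)[s]
    ped <- build_pedigree(make_random_pedigree(n, seed = s + 10))
    A <- relationship_matrix(ped)
    Ai <- relationship_inverse(ped)
    expect_lt(max(abs(as.matrix(Ai %*% A) - diag(n))), 1e-8)
    expect_silent(chol(A))  # symmetric positive definite
    # log-determinant tracked for the REML engine agrees with dense
    expect_equal(attr(Ai, "logdet"), as.numeric(determinant(A)$modulus),
                 tolerance = 1e-8)
  }
})

test_that("inbreeding coefficients are exact on a full-sib mating", {
  # full sibs a,b (parents m,f); their offspring k has F = 0.25
  ped <- build_pedigree(data.frame(
    individual = c("a", "b", "k"),
    mother = c("m", "m", "a"),
    father = c("f", "f", "b")
  ))
  expect_equal(ped$inbreeding[match("k", ped$id)], 0.25)
  A <- relationship_matrix(ped)
  expect_equal(A["k", "k"], 1.25)
  Ai <- relationship_inverse(ped)
  expect_lt(max(abs(as.matrix(Ai %*% A) - diag(nrow(A)))), 1e-10)
})

test_that("triplet export round-trips a sparse matrix", {
  ped <- build_pedigree(make_random_pedigree(40, seed = 2))
  Ai <- relationship_inverse(ped)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_triplets(Ai, path)
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  rebuilt <- Matrix::sparseMatrix(i = tb$i, j = tb$j, x = tb$value,
                                  dims = dim(Ai), symmetric = TRUE)
  expect_lt(max(abs(as.matrix(rebuilt) - as.matrix(Ai))), 1e-12)
})
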