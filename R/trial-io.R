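#' Progeny-trial dataset
#'
#' Couples a phenotype table with its pedigree. The phenotype table is one
#' row per tree with identifier columns `tree_id`, `mother_id`, `population`,
#' `site`, `block` and one numeric column per trait; a missing phenotype is
#' `NA` (never 0). Blocks are interpreted within site (the pair
#' `(site, block)` is the experimental unit of the block effect), matching a
#' randomized incomplete-block, single-tree-plot layout. Population labels
#' are free strings: the genetic-cluster labels of the Norway spruce breeding
#' material (CSE, RusBal, NPL, CEU, CSE-ALP, ALP) are typical values, not a
#' closed set.
#'
#' @param phenotypes Data frame as described above.
#' @param pedigree A [build_pedigree()] object, or a data frame with columns
#'   `individual`, `mother`, `father` (`0`/empty/`NA` = unknown parent).
#' @param traits Optional character vector naming the trait columns
#'   (default: every numeric column that is not an identifier).
#' @return An object of class `qg_trial`: a list with elements `data`
#'   (tibble), `pedigree` (`qg_pedigree`) and `traits`.
#' @export
trial_data <- function(phenotypes, pedigree, traits = NULL) {
  req <- c("tree_id", "mother_id", "population", "site", "block")
  missing_cols <- setdiff(req, names(phenotypes))
  if (length(missing_cols) > 0) {
    stop("phenotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(phenotypes) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(req[-1]), as.character),
                  tree_id = as.character(.data$tree_id))
  if (any(duplicated(data$tree_id))) {
    stop("duplicate tree_id in phenotype table: ",
         paste(unique(data$tree_id[duplicated(data$tree_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(traits)) {
    traits <- names(data)[vapply(data, is.numeric, logical(1))]
    traits <- setdiff(traits, req)
  }
  if (length(traits) == 0) stop("no trait columns found", call. = FALSE)

  if (!inherits(pedigree, "qg_pedigree")) pedigree <- build_pedigree(pedigree)
  unknown_mother <- setdiff(stats::na.omit(unique(data$mother_id)), pedigree$id)
  if (length(unknown_mother) > 0) {
    stop("mother(s) referenced in phenotypes but absent from pedigree: ",
         paste(utils::head(unknown_mother, 5), collapse = ", "), call. = FALSE)
  }
  unknown_tree <- setdiff(data$tree_id, pedigree$id)
  if (length(unknown_tree) > 0) {
    stop("phenotyped tree(s) absent from pedigree: ",
         paste(utils::head(unknown_tree, 5), collapse = ", "), call. = FALSE)
  }
  n_nopop <- sum(is.na(data$population))
  if (n_nopop > 0) {
    message(n_nopop, " tree(s) lack a population assignment; they are kept ",
            "but dropped from population-structure models")
  }
  structure(list(data = data[c(req, traits)], pedigree = pedigree,
                 traits = traits),
            class = "qg_trial")
}

#' @export
print.qg_trial <- function(x, ...) {
  d <- x$data
  cat("<qg_trial>", nrow(d), "trees,", nrow(x$pedigree), "pedigree members\n")
  cat("  sites:      ", paste(sort(unique(d$site)), collapse = ", "), "\n")
  cat("  populations:", paste(sort(unique(d$population)), collapse = ", "), "\n")
  cat("  traits:     ", paste(x$traits, collapse = ", "), "\n")
  invisible(x)
}

#' Read a progeny trial from delimited text files
#'
#' The phenotype and pedigree files are comma- or tab-delimited (auto-
#' detected from the header line) with one header row. The pedigree file has
#' columns `individual`, `mother`, `father`, with `0` or an empty field for
#' an unknown parent. An optional population-assignment file with columns
#' `tree_id`, `population` overrides or supplies the population column.
#' Missing phenotypes are empty fields or `NA`.
#'
#' @param phenotype_path,pedigree_path,population_path File paths.
#' @return A [trial_data()] object.
#' @export
read_trial <- function(phenotype_path, pedigree_path, population_path = NULL) {
  phen <- read_delim_auto(phenotype_path)
  ped <- read_delim_auto(pedigree_path)
  if (!is.null(population_path)) {
    pop <- read_delim_auto(population_path)
    stopifnot(all(c("tree_id", "population") %in% names(pop)))
    phen$population <- NULL
    phen <- dplyr::left_join(
      phen, dplyr::mutate(pop, tree_id = as.character(.data$tree_id)),
      by = "tree_id"
    )
  }
  trial_data(phen, ped)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    na = c("", "NA"), progress = FALSE) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.character), as.character))
}

#' Write a progeny trial to delimited text files
#'
#' Serializes the phenotype and pedigree tables with full numeric precision,
#' so that `read_trial()` on the written files reproduces the dataset
#' exactly.
#'
#' @param trial A [trial_data()] object.
#' @param phenotype_path,pedigree_path Output file paths.
#' @return Named character vector of the paths, invisibly.
#' @export
write_trial <- function(trial, phenotype_path, pedigree_path) {
  stopifnot(inherits(trial, "qg_trial"))
  readr::write_csv(trial$data, phenotype_path)
  ped <- tibble::tibble(individual = trial$pedigree$id,
                        mother = trial$pedigree$mother,
                        father = trial$pedigree$father)
  readr::write_csv(ped, pedigree_path)
  invisible(c(phenotypes = phenotype_path, pedigree = pedigree_path))
}

#' Drop populations represented by too few half-sib families
#'
#' Populations with fewer distinct mothers than `min_families` are removed
#' before analysis, since variance components and fixed population contrasts
#' are not reliably estimable for them. A message reports how many trees and
#' families were dropped per population.
#'
#' @param trial A [trial_data()] object.
#' @param min_families Minimum number of distinct families per population
#'   (default 10).
#' @return The filtered [trial_data()] object.
#' @export
filter_small_populations <- function(trial, min_families = 10) {
  stopifnot(inherits(trial, "qg_trial"), min_families >= 1)
  counts <- trial$data |>
    dplyr::filter(!is.na(.data$population)) |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(n_families = dplyr::n_distinct(.data$mother_id),
                     n_trees = dplyr::n(), .groups = "drop")
  drop <- counts |> dplyr::filter(.data$n_families < min_families)
  if (nrow(drop) == nrow(counts)) {
    stop("all populations have fewer than ", min_families,
         " families; nothing left to analyse", call. = FALSE)
  }
  if (nrow(drop) > 0) {
    message("dropping population(s) ",
            paste(sprintf("%s (%d families, %d trees)", drop$population,
                          drop$n_families, drop$n_trees), collapse = ", "))
    trial$data <- trial$data |>
      dplyr::filter(is.na(.data$population) |
                      !.data$population %in% drop$population)
  }
  trial
}
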