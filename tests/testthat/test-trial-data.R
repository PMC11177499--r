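toy_files <- function(dir, delim = ",") {
  phen <- file.path(dir, "phen.csv")
  ped <- file.path(dir, "ped.csv")
  writeLines(gsub(",", delim, c(
    "tree_id,mother_id,population,site,block,DBH21",
    "t1,m1,CSE,S1,B1,101.5",
    "t2,m1,CSE,S1,B1,",
    "t3,m2,ALP,S1,B1,98.25"
  )), phen)
  writeLines(gsub(",", delim, c(
    "individual,mother,father",
    "t1,m1,0", "t2,m1,0", "t3,m2,0"
  )), ped)
  c(phen = phen, ped = ped)
}

test_that("a toy trial parses with families, missing values and founders", {
  for (delim in c(",", "\t")) {
    fp <- toy_files(withr::local_tempdir(), delim)
    tr <- read_trial(fp["phen"], fp["ped"])
    expect_s3_class(tr, "qg_trial")
    expect_equal(nrow(tr$data), 3)
    expect_equal(dplyr::n_distinct(tr$data$mother_id), 2)
    expect_equal(tr$traits, "DBH21")
    # missing phenotype is NA, not 0
    expect_true(is.na(tr$data$DBH21[tr$data$tree_id == "t2"]))
    expect_equal(tr$data$DBH21[tr$data$tree_id == "t3"], 98.25)
    # implicit founders m1, m2 present in the pedigree
    expect_true(all(c("m1", "m2") %in% tr$pedigree$id))
  }
})

test_that("validation failures are hard errors", {
  fp <- toy_files(withr::local_tempdir())
  # a tree listed twice for the trait
  phen2 <- readLines(fp["phen"])
  writeLines(c(phen2, "t1,m1,CSE,S1,B1,102.0"), fp["phen"])
  expect_error(read_trial(fp["phen"], fp["ped"]), "duplicate tree_id")

  # unknown mother referenced in phenotypes but absent from pedigree
  fp2 <- toy_files(withr::local_tempdir())
  writeLines(c(readLines(fp2["phen"]), "t4,m9,CSE,S1,B1,100.0"), fp2["phen"])
  expect_error(read_trial(fp2["phen"], fp2["ped"]), "absent from pedigree")
})

test_that("an external population table overrides labels", {
  fp <- toy_files(withr::local_tempdir())
  popf <- file.path(dirname(fp["phen"]), "pop.csv")
  writeLines(c("tree_id,population", "t1,NPL", "t2,NPL", "t3,CEU"), popf)
  tr <- read_trial(fp["phen"], fp["ped"], popf)
  expect_equal(sort(unique(tr$data$population)), c("CEU", "NPL"))
})

test_that("write -> read round-trips a simulated trial losslessly", {
  sim <- simulate_trial(sim_config(
    n_populations = 3, families_per_population = 4, offspring_per_family = 4,
    n_sites = 2, blocks_per_site = 2,
    traits = list(default_trait(name = "Y", sigma2_pop = 50)),
    missing_rate = 0.1, seed = 5
  ))
  dir <- withr::local_tempdir()
  write_trial(sim$trial, file.path(dir, "p.csv"), file.path(dir, "g.csv"))
  back <- read_trial(file.path(dir, "p.csv"), file.path(dir, "g.csv"))
  expect_equal(as.data.frame(back$data), as.data.frame(sim$trial$data))
  expect_equal(back$pedigree$id, sim$trial$pedigree$id)
  expect_equal(back$pedigree$mother, sim$trial$pedigree$mother)
})

test_that("small populations are dropped by family count", {
  # a CSE-like large population plus a 3-family one mirrors the exclusion rule
  hs <- make_halfsib_trial(nf = 23, no = 4, n_pop = 1, seed = 3)
  tr <- hs$trial
  tr$data$population <- ifelse(tr$data$mother_id %in%
                                 sprintf("M%03d", 1:20), "CSE", "ROMlike")
  filtered <- suppressMessages(filter_small_populations(tr, min_families = 10))
  expect_equal(unique(filtered$data$population), "CSE")
  expect_equal(nrow(filtered$data), 20 * 4)

  # min_families = 1 keeps everything
  same <- filter_small_populations(tr, min_families = 1)
  expect_equal(nrow(same$data), nrow(tr$data))

  # everything too small -> hard error
  expect_error(filter_small_populations(tr, min_families = 100),
               "nothing left")
})

test_that("filtering matches a brute-force recount on random family sizes", {
  set.seed(11)
  for (rep in 1:5) {
    n_pop <- sample(3:6, 1)
    fams_per_pop <- sample(2:12, n_pop, replace = TRUE)
    rows <- list()
    mid <- 0
    for (p in seq_len(n_pop)) {
      for (f in seq_len(fams_per_pop[p])) {
        mid <- mid + 1
        n_off <- sample(1:3, 1)
        rows[[length(rows) + 1]] <- data.frame(
          mother_id = sprintf("M%04d", mid),
          population = sprintf("P%d", p), n_off = n_off
        )
      }
    }
    fam <- dplyr::bind_rows(rows)
    phen <- fam[rep(seq_len(nrow(fam)), fam$n_off), ]
    phen$tree_id <- sprintf("T%05d", seq_len(nrow(phen)))
    phen$site <- "S1"; phen$block <- "B1"; phen$Y <- rnorm(nrow(phen))
    tr <- trial_data(phen[, c("tree_id", "mother_id", "population", "site",
                              "block", "Y")],
                     data.frame(individual = phen$tree_id,
                                mother = phen$mother_id, father = NA))
    min_fam <- sample(2:8, 1)
    keep_pop <- names(which(tapply(fam$mother_id, fam$population,
                                   function(m) length(unique(m))) >= min_fam))
    if (length(keep_pop) == 0) next
    got <- suppressMessages(filter_small_populations(tr, min_fam))
    expect_setequal(unique(got$data$population), keep_pop)
    expect_equal(nrow(got$data),
                 sum(phen$population %in% keep_pop))
  }
})

test_that("run configuration round-trips through YAML", {
  cfg <- run_config(model_variant = "A", traits = c("DBH", "DENS"),
                    k_folds = 4, seed = 9, min_families_per_population = 5)
  path <- withr::local_tempfile(fileext = ".yml")
  write_run_config(cfg, path)
  back <- read_run_config(path)
  expect_equal(back, cfg)
  expect_error(run_config(k_folds = 1), "k_folds")
})
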