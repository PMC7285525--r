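test_that("universe and reconstructions are deterministic under a seed", {
  u1 <- universe_spec(n_species = 4, seed = 9)
  u2 <- universe_spec(n_species = 4, seed = 9)
  expect_identical(u1, u2)
  expect_identical(generate_toy_reconstructions(u1),
                   generate_toy_reconstructions(u2))
  expect_identical(generate_diet(u1), generate_diet(u2))
  u3 <- universe_spec(n_species = 4, seed = 10)
  expect_false(identical(u1$secretion_map, u3$secretion_map))
})

test_that("secretion map referencing unknown metabolites is rejected", {
  expect_error(
    universe_spec(n_species = 2, secretion_map = list(
      Species_01 = c(unobtainium = 2))),
    "unknown metabolites")
})

test_that("strain networks are feasible and strains differ", {
  u <- small_universe()
  rec <- generate_toy_reconstructions(u)
  diet <- generate_diet(u)
  for (sp in names(rec)) {
    for (m in rec[[sp]]) {
      fed <- suppressWarnings(apply_diet(
        m, stats::setNames(diet$uptake_bound, diet$metabolite)))
      expect_identical(fba(fed)$status, "optimal")
      expect_true("BIOMASS" %in% m$reactions$id)
    }
    expect_false(setequal(rec[[sp]][[1]]$reactions$id,
                          rec[[sp]][[2]]$reactions$id))
  }
})

test_that("single-strain maximal secretion equals yield times uptake", {
  u <- universe_spec(n_species = 1, strains_per_species = 1,
                     diet_metabolites = "glc",
                     secretion_map = list(Species_01 = c(ac = 1)))
  m <- generate_toy_reconstructions(u)[[1]][[1]]
  fed <- apply_diet(m, c(glc = 10))
  # biomass not forced, so all substrate can go to secretion: 1 * 10
  expect_equal(fva(fed, "EX_ac_e")$max, 10, tolerance = 1e-9)
})

test_that("halving a diet bound halves an NMPC fed solely by it", {
  u <- universe_spec(n_species = 1, strains_per_species = 1,
                     diet_metabolites = "glc",
                     secretion_map = list(Species_01 = c(ac = 1.5)))
  pans <- lapply(generate_toy_reconstructions(u), build_pan_species)
  ab <- c(Species_01 = 1)
  n1 <- compute_nmpc(build_community(pans, ab, diet = c(glc = 8)))
  n2 <- compute_nmpc(build_community(pans, ab, diet = c(glc = 4)))
  # secretion after the fixed biomass demand scales linearly in supply
  expect_equal(n1[["ac"]], 1.5 * (8 - 0.4), tolerance = 1e-9)
  expect_equal(n2[["ac"]], 1.5 * (4 - 0.4), tolerance = 1e-9)
})

test_that("diet has one positive row per diet metabolite", {
  u <- universe_spec(n_species = 2,
                     diet_metabolites = c("a", "b", "c", "d", "e"))
  d <- generate_diet(u)
  expect_identical(nrow(d), 5L)
  expect_true(all(d$uptake_bound > 0 & is.finite(d$uptake_bound)))
})

test_that("cohorts are byte-identical under a fixed seed", {
  u <- universe_spec(n_species = 6, seed = 2)
  cs <- cohort_spec(n_cases = 10, n_controls = 10, seed = 33)
  c1 <- generate_cohort(cs, u)
  c2 <- generate_cohort(cs, u)
  expect_identical(c1, c2)
  d1 <- tempfile()
  d2 <- tempfile()
  write_cohort(c1, d1)
  write_cohort(c2, d2)
  expect_identical(readLines(file.path(d1, "counts.tsv")),
                   readLines(file.path(d2, "counts.tsv")))
})

test_that("count rows sum to the sampled read depth exactly", {
  sc <- small_cohort()
  expect_identical(unname(rowSums(sc$cohort$counts)),
                   as.numeric(sc$cohort$metadata$total_reads))
  expect_true(all(sc$cohort$counts >= 0))
})

test_that("degenerate cohorts are refused", {
  expect_error(cohort_spec(n_cases = 2, n_controls = 1), "degenerate")
  expect_error(cohort_spec(taxon_effects = c(Species_01 = -2)),
               "positive")
})

test_that("a planted odds ratio is recovered at large n", {
  u <- universe_spec(n_species = 10, seed = 5)
  cs <- cohort_spec(n_cases = 500, n_controls = 500,
                    taxon_effects = c(Species_01 = 2.04), seed = 77)
  ch <- generate_cohort(cs, u)
  rel <- to_relative(taxonomic_profile(ch$counts))
  grp <- as.numeric(ch$metadata$group == "PD")
  X <- cbind(`(Intercept)` = 1, group = grp)
  fit <- fit_fracreg(rel[, "Species_01"], X)
  expect_equal(unname(exp(coef(fit)["group"])), 2.04, tolerance = 0.09)
})
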