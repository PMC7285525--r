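test_that("pan merge of one strain reproduces the strain", {
  s <- yield_strain("Lactobacillus_gasseri", 1, bcoef = 1.4, yield = 0.7)
  pan <- build_pan_species(list(s))
  expect_setequal(pan$reactions$id, s$reactions$id)
  key <- function(m) {
    st <- m$stoich[order(m$stoich$reaction, m$stoich$metabolite), ]
    rownames(st) <- NULL
    st
  }
  expect_equal(key(pan), key(s))
  expect_equal(fba(pan)$objective, fba(s)$objective, tolerance = 1e-9)
  expect_identical(attr(pan, "species_id"), "Lactobacillus_gasseri")
})

test_that("pan-biomass coefficients are strain averages", {
  s1 <- yield_strain("X", 1, bcoef = 1)
  s2 <- yield_strain("X", 2, bcoef = 3)
  pan <- build_pan_species(list(s1, s2))
  co <- pan$stoich[pan$stoich$reaction == "BIOMASS", ]
  expect_equal(co$coef[co$metabolite == "glc_c"], -2) # mean of 1 and 3
  expect_equal(co$coef[co$metabolite == "biomass_c"], 1)
})

test_that("bounds merge to the widest interval; conflicts are errors", {
  s1 <- yield_strain("X", 1)
  s2 <- yield_strain("X", 2)
  s2$reactions$lb[s2$reactions$id == "EX_glc_e"] <- -20
  pan <- build_pan_species(list(s1, s2))
  expect_equal(pan$reactions$lb[pan$reactions$id == "EX_glc_e"], -20)
  s3 <- yield_strain("X", 3, yield = 0.5) # different SEC_but stoich
  expect_error(build_pan_species(list(s1, s3)), "SEC_but")
})

test_that("pan capability dominates every strain (reaction union)", {
  u <- small_universe()
  rec <- generate_toy_reconstructions(u)
  diet <- stats::setNames(generate_diet(u)$uptake_bound,
                          generate_diet(u)$metabolite)
  for (sp in names(rec)) {
    pan <- build_pan_species(rec[[sp]])
    # the full diet lists substrates some strains cannot import; those
    # are skipped with a warning, which is expected here
    pan_obj <- suppressWarnings(fba(apply_diet(pan, diet))$objective)
    for (s in rec[[sp]]) {
      expect_gte(pan_obj,
                 suppressWarnings(fba(apply_diet(s, diet))$objective) -
                   1e-9)
    }
  }
})

test_that("species name matching is normalised, reported and safe", {
  m <- match_species_names(
    c("Akkermansia_muciniphila", "Prevotella copri", "Unknown_bug"),
    c("Akkermansia muciniphila", "Prevotella_copri", "Bacteroides dorei"))
  expect_identical(
    unname(m$matched[c("Akkermansia_muciniphila", "Prevotella copri")]),
    c("Akkermansia muciniphila", "Prevotella_copri"))
  expect_identical(m$unmatched, "Unknown_bug")
  # idempotent on already-matched labels
  m2 <- match_species_names(unname(m$matched), unname(m$matched))
  expect_identical(length(m2$unmatched), 0L)
  # bracketed qualifiers are stripped
  m3 <- match_species_names("Clostridium [cluster IV] leptum",
                            "clostridium_leptum")
  expect_identical(length(m3$unmatched), 0L)
  expect_error(
    match_species_names("Roseburia", c("roseburia", "Roseburia_")),
    "ambiguous")
})

test_that("community assembly applies threshold, renormalises, and wires", {
  u <- small_universe()
  pans <- lapply(generate_toy_reconstructions(u), build_pan_species)
  diet <- generate_diet(u)
  ab <- c(Species_01 = 0.6, Species_02 = 0.3, Species_03 = 0.00005,
          Ghost_species = 0.09995)
  cm <- suppressWarnings(build_community(pans, ab, diet = diet))
  sp <- attr(cm, "species")
  expect_setequal(names(sp), c("Species_01", "Species_02"))
  expect_equal(sum(sp), 1, tolerance = 1e-12)
  expect_identical(attr(cm, "dropped")$unmatched, "Ghost_species")
  expect_identical(attr(cm, "dropped")$below_threshold, "Species_03")
  # community biomass coefficients are the renormalised abundances
  co <- cm$stoich[cm$stoich$reaction == "communityBiomass", ]
  expect_equal(sum(-co$coef), 1, tolerance = 1e-12)
  expect_equal(cm$reactions$lb[cm$reactions$id == "communityBiomass"], 0.4)
  expect_equal(cm$reactions$ub[cm$reactions$id == "communityBiomass"], 1)
  # single species: coefficient exactly one
  cm1 <- suppressWarnings(
    build_community(pans, c(Species_01 = 0.2), diet = diet))
  expect_equal(unname(attr(cm1, "species")), 1)
  expect_error(build_community(pans, c(Ghost = 1)), "no species")
})

test_that("single-species community NMPC equals standalone FVA", {
  u <- universe_spec(n_species = 2, strains_per_species = 2, seed = 8)
  pans <- lapply(generate_toy_reconstructions(u), build_pan_species)
  diet <- stats::setNames(generate_diet(u)$uptake_bound,
                          generate_diet(u)$metabolite)
  cm <- suppressWarnings(
    build_community(pans, c(Species_01 = 1), diet = diet))
  nm <- compute_nmpc(cm)
  expect_true(attr(nm, "feasible"))
  # standalone: same diet, biomass flux forced into the community interval
  solo <- suppressWarnings(apply_diet(pans$Species_01, diet))
  solo$reactions$lb[solo$reactions$id == "BIOMASS"] <- 0.4
  solo$reactions$ub[solo$reactions$id == "BIOMASS"] <- 1
  for (met in names(nm)) {
    ex <- paste0("EX_", met, "_e")
    if (!ex %in% solo$reactions$id) next # diet passthrough metabolites
    solo_max <- fva(solo, ex)$max
    dietin <- if (met %in% names(diet)) diet[[met]] else 0
    expect_equal(nm[[met]], solo_max + dietin, tolerance = 1e-8)
  }
})

test_that("relaxing the diet never decreases an NMPC", {
  u <- small_universe()
  pans <- lapply(generate_toy_reconstructions(u), build_pan_species)
  diet <- generate_diet(u)
  ab <- c(Species_01 = 0.5, Species_02 = 0.3, Species_03 = 0.2)
  n1 <- compute_nmpc(build_community(pans, ab, diet = diet))
  rich <- transform(diet, uptake_bound = uptake_bound * 2)
  n2 <- compute_nmpc(build_community(pans, ab, diet = rich))
  expect_true(all(n2[names(n1)] >= n1 - 1e-8))
})

test_that("empty diets make communities infeasible, not silently zero", {
  u <- small_universe()
  pans <- lapply(generate_toy_reconstructions(u), build_pan_species)
  cm <- build_community(pans, c(Species_01 = 1))
  nm <- compute_nmpc(cm) # all uptakes closed, biomass >= 0.4 impossible
  expect_false(attr(nm, "feasible"))
  expect_true(all(is.na(nm)))
  expect_warning(
    apply_diet(cm, c(not_a_metabolite = 5)), "skipped")
  expect_error(apply_diet(cm, c(glc = -1)), "negative")
})

test_that("a metabolite no included species can produce has NMPC 0", {
  s <- yield_strain("X", 1)
  # exchange for acetate exists but nothing produces it
  s$metabolites <- rbind(s$metabolites,
                         data.frame(id = "ac_e", compartment = "e"))
  s$reactions <- rbind(s$reactions,
                       data.frame(id = "EX_ac_e", lb = 0, ub = 1000,
                                  obj = 0))
  s$stoich <- rbind(s$stoich,
                    data.frame(reaction = "EX_ac_e", metabolite = "ac_e",
                               coef = -1))
  pan <- build_pan_species(list(s))
  cm <- build_community(list(X = pan), c(X = 1), diet = c(glc = 10))
  nm <- compute_nmpc(cm)
  expect_equal(nm[["ac"]], 0, tolerance = 1e-9)
  expect_gt(nm[["but"]], 0)
})

test_that("relative reaction abundances follow the weighted presence sum", {
  u <- small_universe()
  pans <- lapply(generate_toy_reconstructions(u), build_pan_species)
  ab <- c(Species_01 = 0.7, Species_02 = 0.3)
  rra <- relative_reaction_abundance(pans, ab)
  expect_true(all(rra >= 0 & rra <= 1 + 1e-12))
  expect_equal(rra[["BIOMASS"]], 1) # biomass present in every species
  only1 <- setdiff(pans$Species_01$reactions$id,
                   pans$Species_02$reactions$id)
  for (rx in only1) expect_equal(rra[[rx]], 0.7)
})
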