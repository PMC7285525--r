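# Shared fixtures, built in code once per test run.

# Linear chain: glucose uptake (bound 10) -> biomass, unit yield.
chain_model <- function(uptake = 10) {
  metabolic_model(
    id = "chain",
    metabolites = data.frame(id = c("glc_e", "glc_c"),
                             compartment = c("e", "c")),
    reactions = data.frame(id = c("EX_glc_e", "GLCt", "BIOMASS"),
                           lb = c(-uptake, 0, 0), ub = c(1000, 1000, 1000),
                           obj = c(0, 0, 1)),
    stoich = data.frame(
      reaction   = c("EX_glc_e", "GLCt", "GLCt", "BIOMASS"),
      metabolite = c("glc_e", "glc_e", "glc_c", "glc_c"),
      coef       = c(-1, -1, 1, -1)))
}

# A strain with explicit biomass coefficient and one secretion with a
# given yield, for pan-merge arithmetic tests.
yield_strain <- function(species, strain, bcoef = 1, yield = 1,
                         extra_reaction = FALSE) {
  mets <- data.frame(
    id = c("glc_e", "glc_c", "biomass_c", "but_e",
           if (extra_reaction) "ac_e"),
    compartment = c("e", "c", "c", "e", if (extra_reaction) "e"))
  rx <- list(
    data.frame(id = "EX_glc_e", lb = -10, ub = 1000, obj = 0),
    data.frame(id = "T_glc", lb = 0, ub = 1000, obj = 0),
    data.frame(id = "BIOMASS", lb = 0, ub = 1000, obj = 1),
    data.frame(id = "EX_biomass_e", lb = 0, ub = 1000, obj = 0),
    data.frame(id = "SEC_but", lb = 0, ub = 1000, obj = 0),
    data.frame(id = "EX_but_e", lb = 0, ub = 1000, obj = 0))
  st <- list(
    data.frame(reaction = "EX_glc_e", metabolite = "glc_e", coef = -1),
    data.frame(reaction = "T_glc", metabolite = c("glc_e", "glc_c"),
               coef = c(-1, 1)),
    data.frame(reaction = "BIOMASS",
               metabolite = c("glc_c", "biomass_c"), coef = c(-bcoef, 1)),
    data.frame(reaction = "EX_biomass_e", metabolite = "biomass_c",
               coef = -1),
    data.frame(reaction = "SEC_but", metabolite = c("glc_c", "but_e"),
               coef = c(-1, yield)),
    data.frame(reaction = "EX_but_e", metabolite = "but_e", coef = -1))
  if (extra_reaction) {
    rx <- c(rx, list(
      data.frame(id = "SEC_ac", lb = 0, ub = 1000, obj = 0),
      data.frame(id = "EX_ac_e", lb = 0, ub = 1000, obj = 0)))
    st <- c(st, list(
      data.frame(reaction = "SEC_ac", metabolite = c("glc_c", "ac_e"),
                 coef = c(-1, 1)),
      data.frame(reaction = "EX_ac_e", metabolite = "ac_e", coef = -1)))
  }
  metabolic_model(sprintf("%s__strain%d", species, strain), mets,
                  do.call(rbind, rx), do.call(rbind, st))
}

small_universe <- function(seed = 5, n_species = 3) {
  universe_spec(n_species = n_species, strains_per_species = 2, seed = seed)
}

small_cohort <- function(seed = 11, n = 40, n_species = 8) {
  u <- universe_spec(n_species = n_species, seed = 5)
  list(universe = u,
       cohort = generate_cohort(
         cohort_spec(n_cases = n / 2, n_controls = n / 2, seed = seed), u))
}
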