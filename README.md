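# gutflux

Case-control gut microbiome studies routinely find taxa whose relative
abundances differ between patients and controls, but a list of shifted
genera says little about what the community *does*. `gutflux` implements a
two-tier analysis that connects composition to predicted metabolic
function, motivated by studies of the Parkinson's disease gut microbiome:

1. **Compositional tier.** Per-taxon relative abundances are fractional
   responses in [0, 1], analysed with semiparametric fractional logit
   regressions: the quasi log-likelihood

   ```
   ln L = Σ_j [ y_j ln G(x_j'β) + (1 − y_j) ln(1 − G(x_j'β)) ]
   ```

   with logistic `G` is maximised by IRLS; only the conditional mean
   `E[y|x] = G(x'β)` is assumed, and inference uses an HC1 sandwich
   covariance, so the method is robust to the heteroscedasticity and
   overdispersion typical of microbiome data. Coefficients exponentiate to
   odds ratios on the read-assignment probability scale: for group means
   `ȳ_cases` and `ȳ_controls`,
   `OR = ȳ_cases (1 − ȳ_controls) / (ȳ_controls (1 − ȳ_cases))`.
   Age enters as a restricted cubic spline (3 knots at the 5th/50th/95th
   percentiles), batch as fixed effects, read counts as covariates;
   interaction blocks are tested jointly by robust Wald tests, and
   screening families are corrected with Benjamini-Hochberg FDR control.
   Alpha diversity (richness, Shannon, Pielou evenness) and Bray-Curtis
   beta diversity with ANOSIM/PERMANOVA permutation tests round out the
   tier.

2. **Metabolic tier.** Strain-level genome-scale reconstructions (SBML
   L3/FBC or JSON) are merged into pan-species models (reaction union,
   widest bounds, averaged biomass), then assembled per sample into a
   compartmentalised community model: species below a relative abundance
   of 1e-4 are removed, the remaining abundances are renormalised to one
   and written into the community biomass reaction, whose flux is bounded
   to [0.4, 1]/day (faecal excretion once every 2.5 days to once a day).
   Under a diet (maximal uptake per metabolite), the net maximal
   production capacity (NMPC) of each metabolite is the flux variability
   analysis maximum of its fecal exchange. NMPCs are skew-minimising
   log-transformed, screened with batch random-intercept linear mixed
   models (Hausman tests probe the random-effects assumption), and
   attributed to genera via squared Pearson correlations (r > 0.5 flagged
   as a strong, ≥25% variance contribution).

A synthetic-data module generates toy strain networks with analytically
known secretion capacities and Dirichlet-multinomial cohorts with planted
odds ratios, so the whole pipeline is testable end to end without access
to any cohort data.

## Worked example

The textbook fractional-regression example: a taxon with mean relative
abundance 0.04 in cases and 0.02 in controls.

```r
library(gutflux)
y <- c(rep(0.04, 12), rep(0.02, 12))
X <- cbind("(Intercept)" = 1, group = rep(c(1, 0), each = 12))
fit <- fit_fracreg(y, X)
odds_ratio(fit, "group")$or
#> [1] 2.041667
```

The odds that a read is assigned to this taxon are 2.04 times higher in
cases — identical to the closed form `0.04·0.98 / (0.96·0.02)`.

A synthetic cohort, screened and pushed through community modelling:

```r
u      <- universe_spec(n_species = 8, seed = 5)
cohort <- generate_cohort(cohort_spec(n_cases = 60, n_controls = 60,
                                      seed = 11), u)
rel <- mask_outliers(prevalence_filter(
  to_relative(taxonomic_profile(cohort$counts))))
scr <- screen_taxa(rel, cohort$metadata)
head(scr[order(scr$p), c("taxon", "or", "p", "q_value", "significant")], 4)
#>        taxon    or         p   q_value significant
#> 8 Species_08 0.477 1.64e-252 1.31e-251        TRUE
#> 3 Species_03 2.868  1.10e-97  4.39e-97        TRUE
#> 2 Species_02 2.023  3.72e-88  9.92e-88        TRUE
#> 1 Species_01 1.500  5.31e-27  1.06e-26        TRUE
```

The generator planted odds ratios 1.5, 2.04 and 3 on the first three
species; the fitted ORs recover them, and the last species (the
compositional absorber) shows the expected compensating decrease.

```r
pans <- lapply(generate_toy_reconstructions(u), build_pan_species)
diet <- generate_diet(u)
nt   <- nmpc_table(pans, rel, diet)
round(nt$nmpc[1:3, 1:6], 2)
#>          ac   but   for  fru  gaba   glc
#> S0001 36.41 48.56 38.94 8.98 45.93 14.89
#> S0002 36.40 48.55 38.95 8.98 45.91 14.89
#> S0003 36.41 48.56 38.94 8.98 45.92 14.89
```

Each row is one personalised community model; entries are maximal
secretion fluxes (mmol/day) under the generated diet and the community
growth requirement.

`run_pipeline()` chains all stages from one config (see
`?run_pipeline`), and `inst/scripts/gutflux-cli.R` exposes the same runs
from a shell.

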