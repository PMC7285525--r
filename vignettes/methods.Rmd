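---
title: "Models and methods behind gutflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gutflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutflux)
```

`gutflux` couples two analysis tiers for case-control gut microbiome
studies: compositional statistics on relative-abundance tables, and
personalised community constraint-based modelling that turns those
abundances into predicted metabolite secretion capacities. This vignette
explains the underlying models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data module does
and does not emulate.

## Fractional regression for relative abundances

A taxon's relative abundance in a sample is a fraction in [0, 1] — an
estimate of the probability that a classified sequence read is assigned
to that taxon. Modelling such data with Gaussian regressions ignores both
the bounded support and the strong mean-variance coupling; transforming
to log-ratios discards zeros. Fractional regression instead maximises a
Bernoulli-type quasi log-likelihood

$$\ln L = \sum_{j=1}^N \Big[ y_j \ln G(x_j'\beta)
  + (1 - y_j)\ln\big(1 - G(x_j'\beta)\big) \Big],$$

with the logistic link $G$. Only the conditional mean
$E[y\mid x] = G(x'\beta)$ is assumed; no distribution is imposed on $y$,
which makes the estimator robust to heteroscedasticity and
overdispersion, both endemic in microbiome data. With the logit link,
$e^{\beta}$ is an odds ratio on the read-assignment probability scale:
for a binary group indicator and group means $\bar y_1, \bar y_0$, the
saturated fit reproduces
$\mathrm{OR} = \bar y_1(1-\bar y_0)/(\bar y_0(1-\bar y_1))$ exactly
(0.04 vs 0.02 gives 2.04).

**Estimation.** Iteratively reweighted least squares with step-halving
(a quasi-likelihood decrease is never accepted); convergence when the
largest coefficient update falls below 1e-8, with a 100-iteration cap
that flags rather than errors. At the optimum the quasi-score equations
$\sum_j (y_j - G(x_j'\beta))\,x_j = 0$ hold to numerical precision,
which the test suite asserts.

**Inference.** Heteroscedasticity-consistent sandwich covariance with
the HC1 small-sample factor $N/(N-k)$. The robust-variance flavour is a
package choice: HC1 is the common default in applied regression software
and behaved well in the calibration simulations (group-test type-I error
at nominal level; interaction Wald statistics matching their
$\chi^2_{df}$ reference by Kolmogorov-Smirnov at 1000 null replicates,
$n = 300$).

**Design conventions.** The standard adjustment set is: batch as
fixed-effect indicators, total and unclassified read counts entered
linearly (read counts are modelled as covariates rather than removed by
division, because division-based normalisation is biased when the
multinomial assumption fails), sex, BMI, and age as a restricted cubic
spline with three knots at the 5th, 50th and 95th percentiles
(truncated-power parameterisation, linear beyond the boundary knots;
with three knots this is one linear plus one nonlinear column).
Interaction analyses multiply the group indicator into the covariate
columns and test the whole block simultaneously with a robust Wald test.
Analyses are complete-case: rows with missing modelled covariates are
dropped and counted, never imputed.

**Screening.** One regression per retained taxon; the retained set
comes from a strict "detected in more than 50% of samples" prevalence
rule (a taxon present in exactly half the samples is dropped — the rule
is read literally). Outlying abundances more than 4 SD from the pooled
per-taxon mean are masked once, in a single pass; the rule is not
re-iterated on the masked column, and masking is pooled rather than
stratified by group, both deliberate simplifications in the absence of a
stated protocol. P-values are adjusted per family (one family per
predictor of interest) by the Benjamini-Hochberg step-up procedure at
FDR 0.05.

## Diversity

Richness counts detected taxa; Shannon entropy is
$H = -\sum p \ln p$ over nonzero fractions. Pielou evenness is reported
in two variants: the Simpson-based evenness
$(1/\sum p^2)/\text{richness}$ — the package default — and the
conventional Shannon-based $H/\ln(\text{richness})$, which is undefined
for single-taxon samples and returned as missing there. Beta diversity
uses Bray-Curtis dissimilarities with ANOSIM (mid-ranks for ties) and
PERMANOVA through vegan; permutation p-values use the add-one estimator
$(1 + \#\{R^* \ge R\})/(1 + n_{\text{perm}})$ with a default of 999
permutations, so p can never be exactly zero and is bounded below by
$1/(1+n_{\text{perm}})$.

## Constraint-based community modelling

A metabolic reconstruction is encoded in a stoichiometric matrix $S$
(rows metabolites, columns reactions; substrates negative, products
positive). Flux balance analysis maximises a linear objective subject to
steady state $Sv = 0$ and flux bounds; the optimal flux vector need not
be unique but the objective value is. Flux variability analysis (FVA)
minimises and maximises each queried reaction's flux under the same
constraints.

**Pan-species models.** Strain reconstructions of one species are merged
by reaction union; where strains disagree on bounds the widest interval
wins (a capability union), and conflicting stoichiometry under one
reaction id is an error. The pan-biomass reaction averages the strain
biomass coefficients, component-wise over the strains containing each
component. Pan models may overestimate what any single strain can do —
that is inherent to species-level resolution.

**Community assembly.** For one sample, species with relative abundance
below 1e-4 or without a matching reconstruction (deterministic name
normalisation: case-fold, unify spaces/underscores, strip bracketed
qualifiers; ambiguous matches are an error, never silently resolved) are
removed, and the remainder renormalised to sum to one. Each species
keeps its own compartment (id-prefixed); former exchange reactions
become reversible transporters into a shared lumen. Every lumen
metabolite gets a separate diet uptake reaction (flux in [0, uptake];
closed for metabolites absent from the diet — no free lunch) and a
fecal secretion exchange. The community biomass reaction consumes each
species' biomass with its renormalised abundance as stoichiometric
coefficient and is bounded to [0.4, 1] per day, i.e. faecal excretion
between once every 2.5 days and once a day.

**NMPC.** The net maximal production capacity of a metabolite is the FVA
maximum of its fecal exchange under the applied diet and the community
biomass interval. Two readings were possible here: fix community growth
at its optimum before scanning exchanges, or leave growth free within
its interval. The package adopts the interval semantics — growth is a
constraint, not an objective — because the biomass requirement is stated
as a bound; this choice is test-covered (single-species communities
reproduce standalone FVA exactly). Diet metabolites can route through
the lumen to the fecal exchange, so an NMPC of a diet compound includes
passthrough; secreted products of the toy universes are disjoint from
diet compounds, keeping planted capacities analytic. No flux-to-biomass
coupling constraints are imposed. Infeasible communities (e.g. a diet
that cannot sustain the growth requirement) are flagged and excluded
downstream, never reported as zeros.

**LP kernel.** All LPs run on a dense two-phase primal simplex written
for this package (Dantzig pricing, switching to Bland's rule for
guaranteed termination; feasibility tolerance 1e-9). The problems here
are small and dense — tens to a few hundred reactions — where a tableau
method is entirely adequate. Correctness is established against an
independent vertex-enumeration oracle over random networks (agreement to
1e-7 on 50 models in the acceptance suite, plus statuses on infeasible
and unbounded instances).

## NMPC statistics

Raw NMPCs are heavily and heterogeneously skewed. Each metabolite is
transformed as $\log(x + c)$ with $c$ chosen from a declared grid (half
and one times the smallest positive value, plus a 13-point log-spaced
grid from 1e-6 to 1) to minimise absolute sample skewness; the chosen
$c$ is recorded so the transform is invertible. Metabolites with at most
50% nonzero values are dropped, as are those whose observations are
dominated (more than half) by one repeated value — such as pure diet
passthrough capacities — since distributions with many identical values
are unsuitable for regression analysis; then the 4-SD outlier mask is
applied.
Associations use linear mixed models with a batch random intercept
(REML by default; lme4), falling back to OLS with a warning for a single
batch — the random-effect treatment is more powerful than batch dummies
but rests on stronger assumptions, which the Hausman specification test
probes by comparing the two estimators
($H = d'(V_{FE}-V_{RE})^- d$, pseudo-inverse with rank-based degrees of
freedom when the variance difference is singular; ML fits are used for
nesting coherence). Genus-to-metabolite attribution is the pairwise
Pearson correlation on the analysis-ready (transformed, masked) values,
with $r > 0.5$ — at least 25% of variance — flagged as strong; the flag
keys on $r$, not on a separately rounded $r^2$.

## The synthetic-data module

The generator exists so every downstream stage has a ground truth.

*Reconstructions.* Each species gets small strain networks: substrate
uptake exchange, transporter, unit-yield biomass, and one secretion
pathway per secreted metabolite with a specified yield (unit
stoichiometry elsewhere). Later strains gain an alternative substrate
pathway, so pan-merging is nontrivial, and biomass coefficients vary by
strain so pan-averaging is observable. Maximal secretion capacities are
analytic: yield × (uptake − biomass demand).

*Cohorts.* Classified reads follow a Dirichlet-multinomial whose mean
vector is built on the logit scale: per-taxon baselines, plus the
planted group log-odds ratio, covariate terms and per-batch shifts. The
last species absorbs the compositional remainder, which makes the
expected relative abundance of every other taxon exactly the inverse
logit of its linear predictor — so planted odds ratios are recoverable
by the estimator without approximation, and the absorber itself shows a
compensating group effect (it is excluded from null sets in the
calibration tests for that reason). Group effects use the same logit
parameterisation the estimator assumes; the age effect is planted as a
quadratic so the spline machinery is genuinely exercised. Where the
emulated study design reports values they are used as defaults (group
sizes 147/162-scale, age means 69.3/63.3 truncated at 50, ~33% female,
BMI 27.5 ± 4.6, constipation 37%/6%, two batches); depth and dispersion
are reported nowhere, so the defaults — negative-binomial depth with
mean 30,000 and size 10, Dirichlet concentration 300, 8% unclassified
reads — are declared package choices, set once and not tuned.

*What passing tests do not show.* The generator has no phylogenetic
correlation between taxa, no realistic 16S error or chimera profile, no
taxon-specific amplification bias, and its toy networks are orders of
magnitude smaller than curated reconstruction collections. Recovery and
calibration results therefore validate the statistical and numerical
machinery, not the biology of any particular cohort.

## Problem sizes and determinism

The calibration suites run at sizes chosen to make Monte-Carlo error
small relative to the tolerances asserted: 200 simulated cohorts at
200 per group and 30 taxa for coverage/FDR, 1000 replicates for the
Wald null, 150 label-permutation replicates for ANOSIM/PERMANOVA
uniformity, and 50 random networks for solver-oracle agreement. All
generators use self-contained RNG streams keyed by explicit seeds and
never touch the caller's RNG state; identical seeds give byte-identical
outputs, which the suite asserts at file level.

## Known limitations

Fractional regressions model each taxon marginally; no cross-taxon
covariance is estimated. The community model ignores kinetic and
regulatory constraints, as all stoichiometric models do, and NMPC is a
capacity, not a predicted rate. Pan-species merging may credit a species
with pathway combinations no single strain carries. The Hausman test
compares estimators under homoscedastic model-based covariances; with
strong heteroscedasticity its size may drift. The simplex kernel is
dense and intended for models up to a few hundred reactions — genuinely
genome-scale community models (tens of thousands of reactions) would
need a sparse industrial LP solver behind the same interface.
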