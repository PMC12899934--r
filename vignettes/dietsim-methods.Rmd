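---
title: "dietsim: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dietsim: models, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietsim)
```

`dietsim` is a controlled test bed for integrated dietary-pattern
assessment. This vignette is the package's own account of the generative
model, how its defaults were calibrated, the numerical conventions used
throughout, and what the shipped tests do and do not demonstrate about
real dietary data.

## The generative model

Each simulated person-day in one of the four patterns (Mediterranean,
Western, Plant-based, Mixed) is generated as:

1. **Composition.** Food-group shares over the eight groups (Animal,
   Dairy, Fruit, Grain, Legume, Nuts, Oil, Vegetable) are drawn from
   `Dirichlet(alpha0 * base_shares)`. `alpha0 = 12` for every pattern;
   larger values shrink within-pattern compositional spread without moving
   the mean. Base shares are pattern-specific (see *Calibration*).
2. **Quantity.** Total daily food mass (kg/day) is a truncated normal on
   [0.5, 6] kg with pattern-specific location and scale. Truncation
   prevents negative or absurd masses; the bounds bracket plausible adult
   daily food intake including beverages-as-food.
3. **Aggregation.** Consumption is `shares x mass` (kg per group), and
   every derived quantity is an exact weighted sum: nutrients use per-kg
   densities (the database stores per-100 g values; the x10 conversion
   happens in exactly one place, `compute_intakes()`), footprints and cost
   use per-kg emission factors (kg CO2e/kg), water footprints (L/kg) and
   prices (USD/kg). Because aggregation is exact, every stored derived
   field can be re-derived from stored consumption to 1e-9 relative
   tolerance — a property the test suite checks on every population it
   builds.
4. **Demographics.** Age ~ truncated normal on [18, 80] y, BMI on
   [15, 50] kg/m2, sex and tertiary education Bernoulli, income quintile a
   rounded normal clipped to 1..5, season uniform on 1..4. The truncated
   normals are parameterized by their *post-truncation* means: the sampler
   solves for the underlying location so that the realized mean equals the
   target (otherwise a target like age 45.8 +- 11.6 would come out ~0.2 y
   high, and moment-based checks would be systematically biased).
5. **Diversity.** The dietary diversity score (distinct foods per day,
   FAO-style 8–15 range) is a discretized normal (pattern means ~11.0–11.2,
   SD ~2, clipped to [4, 20]). It is a *sampled attribute*, not derived
   from consumption: the model works at food-group resolution, so a
   food-count cannot be computed mechanistically. Analyses that treat
   diversity as an outcome of composition would need a per-food layer this
   package intentionally does not model.
6. **Plant/animal ratio.** Mass ratio of the six plant groups to
   Animal + Dairy, capped (default 100) because near-vegan draws make the
   denominator vanish.

Rows are person-days: `days_per_person` (default 1) simply repeats the
person's demographic block with fresh composition draws, and all
statistics operate on rows.

## Calibration of the shipped defaults

The only quantitative constraints available for the generator are
*pattern-level output means* (energy, protein, iron, calcium, zinc,
vitamin D, B12, GHG, water, cost, diversity) and energy SDs. The
calibration (`scripts/calibrate_defaults.R`, run once; its outputs are the
frozen fixtures in `inst/extdata/`) inverts the generative model
analytically: with shares independent of mass,
`E[X] = E[mass] * (base_shares . density_X)` and the variance follows from
the Dirichlet second moments and the truncated-normal moments. Base shares
and mean mass are fitted per pattern by penalized least squares on the
relative errors, with:

* **Qualitative boxes** that preserve the archetypal orderings — the
  Plant-based pattern has the lowest animal share (~0.06 vs 0.07–0.10
  elsewhere) and the lowest per-kg emissions; Western the highest animal
  share; Mixed sits between. A strictly animal-free "Plant-based" pattern
  is *incompatible* with the published target profile: without animal mass
  the protein target cannot be met except through legume/nut/grain levels
  that overshoot iron by >30%, and the GHG target undershoots by >14%.
  The calibration keeps the tested output targets and treats the
  archetype descriptions as soft constraints; compositional convergence
  across patterns is therefore a *feature of the targets themselves* (the
  published footprints span only ~6%), not an artifact.
* **Hinged errors** so that every per-metric bias stays within ~4% (1.5%
  for energy, whose pooled mean is separately constrained), leaving
  headroom for sampling noise: at n = 375 per pattern, high-CV metrics
  like calcium (CV ~65%) have ~3% standard errors on their cohort means.
* **A sampling-variance penalty** on the zinc/vitamin D/B12 group
  densities. These three nutrients have no published group-level
  densities at all, so the fixture
  (`extension_nutrients_synthetic.csv` — *synthetic*, as the name says) is
  chosen to reproduce the published pattern-level intakes. Because
  Dirichlet shares of rare groups are very noisy (CV ~170% for a 2.5%
  share at `alpha0 = 12`), densities concentrated on rare groups would
  make the pattern means unstable; the penalty spreads them onto common
  groups. The resulting values are calibration artifacts with plausible
  structure (zinc from animal/legume/nuts/grain, B12 from animal/dairy
  plus fortified legume products), not nutritional reference data.

With the frozen defaults, every pattern-level mean lands within +-10% of
its target for the default configuration (checked by the acceptance
suite), with observed worst-case cohort errors of ~8–9% across unseen
seeds.

## Numerical conventions

* **Seeds.** Every stochastic entry point takes a `seed`; `with_seed()`
  restores the caller's RNG state, and pipeline stages derive child seeds
  from the global seed via a stage-name hash (`derive_seed()`), so stages
  can be re-run independently. All derived seeds stay below 2^31.
* **Truncated normals** are sampled by inverse CDF (exact, vectorized).
  Where published moments describe an already-truncated population,
  `rtruncnorm_matched()` solves for the underlying parameters so the
  post-truncation moments match; plain truncation at the published
  parameters would shrink the realized SD (~6% for a bound two SDs from
  the mean) and bias bootstrap SEs low.
* **Bootstrap CIs** use the literal `0.025*B` and `0.975*B` order
  statistics (no interpolation); the SE is the SD of the replicate means
  with Bessel's correction.
* **Chi-square** uses no continuity correction; ANOVA and chi-square are
  implemented from their defining sums and cross-checked in the test suite
  against `chisq.test()` / `aov()` to 1e-8 on random inputs.
* **PCA signs** are fixed by forcing the largest-magnitude loading of each
  component positive, so loadings are comparable across runs.
* **t-SNE** is an exact O(n^2) implementation (perplexity bisection to
  1e-5 entropy tolerance, early exaggeration x4 for 100 iterations,
  momentum 0.5 then 0.8 after iteration 250) and reports the final KL
  divergence. At n = 1500 a full 1000-iteration run takes minutes, so the
  pipeline runs it only when `tsne = TRUE`.
* **Random-forest importance SEs.** The importances are normalized Gini
  (impurity-decrease) values; the SE of the forest mean is estimated from
  K = 20 independent 25-tree sub-forests as `sd(batch means)/sqrt(K)`,
  an unbiased estimator of `sd_tree/sqrt(500)` that does not require
  per-tree importances.
* **Reported percentages** at 1 dp use half-away-from-zero rounding
  applied in two stages (2 dp, then 1 dp), matching the reference
  validation table's convention (which reports a computed -4.55 as -4.6).
  Raw deviations are never altered; only `format_reported_pct()` applies
  the convention.
* **Classification F1 at printed precision.** F1 recomputed from 3-dp
  rounded precision/recall can differ by 1 in the last digit from F1
  computed on the underlying integer confusion counts (0.184 vs 0.185 for
  a 12/23/107 cell); the acceptance tests reconstruct the integer counts,
  which reproduce every printed value.

## Optimization design

The diet decision vector is 8 shares on the simplex with a 0.4 per-group
cap, plus total mass in [0.5, 6] kg. Objectives: adequacy
`f1 = (Fe/EAR + Ca/EAR + Zn/EAR + protein/RDA)/4` for a configurable
reference person (default: female thresholds — the stricter iron case —
and 0.8 g/kg x 70 kg protein), environmental composite
`f2 = (GHG/3.96 + Water/4175)/2` with the published observed maxima as
constants, and `f3 = cost/cost_max` (no published constant exists;
the default is the maximum observed cost of the supplied population,
recorded in run metadata). Protein-energy ratios use the standard 4 kcal/g
Atwater factor.

NSGA-II encodes candidates as 9 genes in [0, 1]: 8 free share genes
repaired onto the capped simplex (clip at 0.4 and renormalize, iterated)
and one mass gene. Energy and protein-ratio constraints use Deb's
feasibility-first domination. The published algorithm settings (population
200, crossover 0.9, mutation 0.1, 100 generations) are kept; the SBX
distribution index is set to `eta_c = 2` because with the conventional
`eta_c = 15` the three weighted-scheme corners of the front do not
converge within a 100-generation budget (weighted-score gaps up to 0.21 vs
the grid oracle; with `eta_c = 2` all gaps are within 0.02 across seeds).
The exhaustive grid oracle enumerates the full capped-simplex grid (step
0.05: ~635k compositions) and exploits the fact that all three objectives
are linear in mass, so the per-composition optimum lies at an endpoint of
the feasible mass interval.

## Scenarios

Scenario mechanics are the least-specified part of the underlying study
design, so they are deliberately simple and fully configurable: the
Mediterranean-shift and plant-forward interventions blend each person's
shares toward the target pattern's base shares with a single
`lambda = 0.5` default; the seasonal intervention applies a shipped
4-season rotation table (fruit/vegetable boosted in season, compensated
from grains); affordability blends toward the cost-minimal feasible diet
found by the grid oracle with weights (0, 0, 1). Total mass per person is
preserved, and all derived fields are recomputed exactly. Published
scenario percentages depend on unpublished mechanics and are treated as
qualitative direction checks only: the tested properties are the identity
at `lambda = 0`, exact share convergence at `lambda = 1`, strictly lower
mean emissions under plant-forward, and strictly lower mean cost under
affordability.

## What the simulation does and does not emulate

The generator reproduces *population-level moments* (pattern means within
+-10%, pooled energy mean/SD) and realistic between-pattern demographic
gradients. It does **not** model: per-food selection within groups (so
dietary diversity is exogenous), nutrient bioavailability (intakes are
gross densities x mass), under-reporting or behavioral dynamics (meal
skipping, weekday/weekend structure), or seasonality of the baseline diet
(season only matters to the seasonal scenario). Consequently, passing
tests demonstrate that the *methods* behave correctly on data with the
published moment structure — not that the moments themselves describe any
real population. Two internal inconsistencies of the reference profile are
worth knowing: simulated iron adequacy prevalence is ~84% (a mean of 24
+- 12 mg/day against an 18 mg female EAR cannot yield ~97%), and the
"Plant-based" pattern is plant-forward rather than vegan (see
*Calibration*).

## Problem sizes used by the shipped tests

Structural tests run on 200-row populations; calibration and
classification properties on the full 1500-row default; determinism on a
complete five-stage pipeline at reduced size (50 per pattern, B = 200,
20 generations); t-SNE contracts at n = 200 with 250–300 iterations. These
sizes were chosen so the full suite exercises every code path, including
the full-scale calibration, while remaining quick enough to run on every
change.
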