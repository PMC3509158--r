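---
title: "Methods: diversity, environment and ecosystem-service multifunctionality in fallows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, environment and ecosystem-service multifunctionality in fallows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallowfun)
```

## The question and the pipeline

Smallholder fallows in the East African highlands are managed in two
contrasting ways: *improved* fallows are planted with fast-growing
leguminous trees and shrubs (typically one to three species, ungrazed),
while *grazed* fallows regenerate spontaneously under livestock grazing and
carry a richer, mostly native flora. Whether the capacity of a fallow to
deliver several ecosystem services at once — its *multifunctionality* — is
driven more by plant diversity or by environmental favorability is the
question this package operationalises.

The pipeline runs from raw survey tables to a model-comparison stage:

1. **Vegetation biomass.** Stems ≥ 2.5 cm DBH get whole-tree aboveground
   biomass from the general humid-region allometry
   $Y = e^{-2.134 + 2.53\,\ln \mathrm{DBH}}$ (kg per stem, DBH in cm);
   everything else goes through biovolume × a growth-form conversion factor.
   Green and woody tissue pools follow from species fractions. All records
   refer to a 100 m² plot, so 1 kg/plot = 0.1 t/ha.
2. **Four ecosystem functions.** Wood biomass (woody tissue of trees and
   large shrubs: stems ≥ 2.5 cm plus the biovolume path of woody species
   with average height ≥ 0.7 m), forage biomass (standing green biomass of
   higher-quality forage species: herbs and sub-0.7 m woody plants with
   green-tissue CP:lignin ≥ 0.8, CP = 6.25 × N), topsoil base cations
   (Mg + Ca + K, meq/100 g, subplot means), and the steady infiltration
   rate (lower asymptote $f_c$ of the Horton equation
   $f(t) = f_c + (f_0 - f_c)e^{-kt}$ fitted per ring-infiltrometer curve,
   averaged over the two subplots).
3. **Diversity.** Species richness counts species holding ≥ 1% of a plot's
   standing green biomass (inclusive). Functional diversity (FD) is the
   summed branch length of the UPGMA dendrogram over the filtered species
   in standardized ln-trait space (green tissue N, lignins, polyphenols).
   Community-weighted means (CWM) are green-biomass-weighted means of
   ln-traits, with group-weighted variants for trees/large shrubs and for
   forage species.
4. **Multifunctionality.** Functions are transformed first (wood
   ln(x + 1); forage and infiltration square root; cations arcsine square
   root against a scale constant of 100). Per type and function the
   *maximum* is the mean of the 3 highest transformed values and the *mean*
   is the overall transformed mean. The two indicators are the proportion
   of the four functions at or above τ·maximum (τ ∈ {0.25, 0.5, 0.75};
   arcsine-square-root transformed for modelling) and the mean percentage
   excess over the means, $E = \tfrac{1}{4}\sum_f 100\,(x_f-\mu_f)/\mu_f$,
   which averages to exactly zero over the plots defining the means.
   Pairwise *jointness* counts plots with both functions of a pair at or
   above the half-maximum or the mean.
5. **Inference.** Per fallow type and indicator: univariate OLS on FD,
   richness, soil carbon and (grazed only) grazing intensity, plus the
   additive bivariate combinations of one diversity and one environmental
   variable — 8 models per indicator for grazed, 5 for improved — reporting
   estimates, t, two-sided P and adjusted R². Correlations carry Fisher-z
   intervals $\tanh(\mathrm{atanh}\,r \pm 1.96/\sqrt{n-3})$; fallow types
   are compared by one-way ANOVA.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| abundance filter | 1% of green biomass, inclusive | rare species bias evenness, not function |
| wood/forage height split | 0.7 m average height | short woody plants yield no usable wood |
| forage quality | CP:lignin ≥ 0.8, inclusive | approximates the lowest quartile boundary; lignin impedes digestion |
| cover-class midpoints | 0.025, 0.095, 0.275, 0.525, 0.825 | 5-point field scale; top class (>65%) read against 100% |
| cations arcsine scale | 100 | values are meq per 100 g; configurable, indicators are recomputed (not rescaled) when it changes |
| thresholds τ | 0.25, 0.5, 0.75 | half-maximum is the headline indicator |
| Horton k bounds | [1e-5, 1] per minute | keeps the asymptote from escaping on short records |
| grazing coding | cover-class midpoint (0.025–0.825) | published intercept/slope magnitudes are consistent with a 0–1 scale |
| soil carbon scale | fraction (g/g) in models | published coefficient magnitudes imply a 0–1 scale; CSVs store percent |

## Numerical choices

* **Horton fits** use concentrated least squares: for fixed $k$ the model
  is linear in $(f_c, f_0)$, solved in closed form; $k$ is found by bounded
  Brent search on the profiled residual sum of squares. This has the same
  objective as a nonlinear least-squares solver but cannot fail to return
  an answer; a constant curve (unidentifiable $k$) falls back to the mean
  of the final quartile of rates, flagged `converged = FALSE`. The original
  analysis pooled curves in a nonlinear mixed model; per-curve independent
  fits give the same per-plot quantity without shrinkage and are testable
  in isolation.
* **FD conventions.** ln-traits are centred and scaled to unit SD across
  the pooled species set of the dataset (not per plot), so FD is comparable
  across plots; Euclidean distances are translation-invariant, which also
  makes the unusual "mean of 1" rescaling phrasing immaterial. Node height
  is the UPGMA merge distance with leaves at height 0, so two species at
  distance $d$ give FD = $2d$; the convention rescales FD by a constant
  only. Species at coincident trait coordinates are collapsed to one leaf
  before clustering: under leaf-count-weighted UPGMA a trait-identical twin
  would reweight later merges even though its own merge has height zero;
  collapsing makes the zero-length-merge invariance exact.
* **Zero-safe log.** Heavily grazed fallows can produce no wood, and
  ln(0) is undefined, so wood uses ln(x + 1). This is a documented
  divergence from a bare "natural log".
* **Inclusive thresholds.** "Above" comparisons are implemented as ≥.
  Boundary ties have probability zero on continuous data; inclusivity makes
  integer-valued test fixtures deterministic.
* **Maxima on the transformed scale.** The mean of the 3 highest values is
  not transform-equivariant, so the scale matters: references and
  indicators are all computed after transformation, matching the stated
  order of operations.

## The synthetic-data generator

There are no deposited field data, so a seeded generator states the world
the analysis assumes: 18 grazed and 21 improved fallows by default, a
45-species pool, and per-type calibration targets equal to the published
means and SDs of the four raw functions (wood 3.0 ± 3.3 / 24.2 ± 5.9 t/ha,
forage 2.4 ± 1.2 / 1.7 ± 1.1 t/ha, cations 4.8 ± 2.2 / 3.7 ± 1.2 meq/100 g,
infiltration 261.8 ± 198.1 / 371.0 ± 148.1 mm/hr for grazed / improved).

Communities come first: grazed plots draw 5–15 species with uneven
Dirichlet (α = 0.7) abundances and a graded grazing class with the moderate
class over-represented (the largest usable group in the field data);
improved plots draw 1–3 dominant planted legumes holding ≥ 80% of green
biomass over a sparse understory. Realized FD is computed from these
communities with the package's own estimator.

Function values are then drawn per plot from **gamma margins
moment-matched to the calibration targets**, linked by a Gaussian copula to
standardized realized FD (grazed) or soil organic carbon (improved). The
copula replaces a literal additive effect on the transformed scale: an
additive construction distorts the raw-scale calibration through
back-transform (Jensen) effects, whereas the copula preserves the margins
exactly while planting a monotone, near-linear dependence — which is what
the recovery tests measure. `effect_fd_grazed = effect_soc_improved = 0.5`
with latent `noise_sd = sqrt(1 - 0.25)` implies a function–covariate
correlation of 0.5, in line with the R² ≈ 0.3 scale of the published
univariate diversity models; `effect = 0` gives exact independence, so the
downstream test's type-I error is nominal. Grazed wood targets are further
scaled by grazing class (×1.4 light, ×1.0 moderate, ×0.6 heavy;
expectation ≈ 1), reproducing the wood–grazing decline.

Records are constructed to realize the targets through the real
estimators: tree stems are drawn (DBH 3–16 cm) until a random 30–70% of a
species' woody target is covered allometrically, the biovolume path carries
the remainder; quality-forage green biomass is allocated to match the
forage target; soil subplot pairs are symmetric about the cation and SOC
targets; two noisy Horton curves per plot have asymptotes averaging to the
infiltration target (f₀ drawn 250–900 mm/hr, k 0.03–0.08 /min, curve noise
10 mm/hr, 16 time points over 150 min). Within-plot variance components
are unpublished, so subplot perturbations are small symmetric fractions
(≤ 8%) of the plot value — a stated choice, not an estimate.

What a green test does **not** establish: the generator has no spatial
layout, no NIR spectra, no multi-year dynamics, no real species
composition, and its trait distributions are invented (only their ranges
and mutual independence are constrained). Recovery of the planted effects
shows the estimators and models are consistent, not that the field effect
sizes are correct; the published regression coefficients and ANOVA F values
derive from undeposited data and are not reproducible at desk scale.

## Known limitations

* The double-count question for species carrying both measured stems and
  biovolume is unresolved in the protocol description; the implementation
  treats recorded biovolume as excluding measured stems, and the generator
  constructs data that way.
* CWM weights default to all species (the ≥ 1% filter is stated explicitly
  only for richness and FD); `diversity_metrics(cwm_filtered = TRUE)`
  applies the filter.
* One published correlation interval (r = 0.562, CI [0.05, 0.84] at
  d.f. = 1,16) is not consistent with the Fisher-z formula that reproduces
  the other five printed intervals; it is excluded from checks.
* `mean_percentage_excess` requires strictly positive transformed means;
  the ln(x + 1) wood transform guarantees this, a strict ln would not.

## A worked run

```{r example, eval = FALSE}
cfg <- generator_config(seed = 42)
ds <- generate_fallow_survey(cfg)
res <- run_pipeline(ds)
res$reference                      # per-type maxima (mean of 3 highest) and means
head(res$indicators)               # both indicators at 25/50/75%
subset(res$models$grazed, indicator == "prop_asin_50" & model == "fd")
```
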