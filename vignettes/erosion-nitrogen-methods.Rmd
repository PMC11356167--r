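---
title: "Methods: simulated erosion-thickness plots and the nitrogen analysis chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated erosion-thickness plots and the nitrogen analysis chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erodyn)
```

`erodyn` implements the computational backbone of a simulated-erosion field
experiment in a dry-hot valley: the tillage-erosion mixing model used to
design erosion-thickness plots, the cut-and-fill geometry used to build
them, a synthetic generator for the study-shaped dataset, and the
statistical chain applied to it (ANOVA with Fisher LSD letters, mineral-N
reduction rates and ratios, community ordination and PERMANOVA, PLS path
modelling). This vignette explains the models, the tunable parameters and
the numerical choices; the package README shows the workflow.

## The tillage-erosion mixing model

On cultivated slopes, erosion removes soil from the surface while annual
tillage keeps homogenising the top `m` cm (the cultivated horizon, 20 cm
here). The horizon therefore keeps its thickness but continuously changes
composition: each year the fraction `d/m` of everything in it is lost with
the eroded surface (where `d` is the mean annual erosion thickness,
0.1 cm/a for the basin the design targets), and tillage then incorporates a
fresh `d`-thick slice of original material newly engulfed at the bottom of
the plow zone. After `n` years the original cultivated horizon contributes

```
h0' = m * (1 - d/m)^n
```

and a slice incorporated in year `k` contributes `d * (1 - d/m)^(n-k)`,
apportioned to whichever original layer(s) it spans. `horizon_composition()`
evaluates this closed form (summing each layer's slice run as a geometric
series); `simulate_mixing()` is the discrete year-by-year oracle. Two
choices are worth stating:

* **Operation order.** Each simulated year erodes first and incorporates
  second, and the newly incorporated slice is *not* eroded in its year of
  incorporation. This is the unique order under which the loop reproduces
  the closed form for `h0` and the 12.12 + 7.88 = 20 cm split at 10 cm of
  cumulative erosion.
* **Layer boundaries.** When the annual slice spans a boundary between
  original layers it is pro-rated between them, which conserves mass for
  arbitrary layering. Conservation (components summing to `m` within
  1e-9 cm) and closed-form/simulator equivalence are enforced by tests
  over a grid of profiles, erosion rates and year counts.

The model runs in whole years, so a treatment depth `D` must be an integer
multiple of `d` (`years_for_erosion()` refuses anything else). Depths below
the declared profile bottom are only usable if the deepest layer is typed
`parent`, in which case it extends indefinitely — matching the role of
parent material as backfill substrate; otherwise the simulator stops with
the year in which the plow zone would exhaust the profile.

## Cut-block geometry and the construction plan

Equivalent layers of a few centimetres cannot be excavated as such. By
volume conservation the thin layer (thickness `h_i'` over the whole
`a x b` plot) is re-cut as a block of the full source-layer thickness
`h_i` with length fixed at `a' = 2` m and width

```
b' = (h_i' * a * b) / (h_i * a')
```

If `b'` exceeds the plot width (which happens for the 40 cm treatment's
parent-material component, a 12.66 cm equivalent drawn from a 10 cm
declared layer), the block is split into equal-width strips with a
warning; volume is unchanged. `construction_plan()` applies this to every
treatment x replicate, assigns treatments to plot positions with a seeded
permutation, and records a parent-material backfill equal to the treatment
depth so that all 50 plot surfaces finish level (cut depth = fill depth).

## What the synthetic generator emulates

The generator exists so the whole statistical chain is exercisable and
testable without any sequencing download. Its defaults encode the study
conditions: 5 erosion-thickness treatments (0-40 cm) x 10 replicate plots,
sampled in a rainy and a dry season.

* **Mineral nitrogen.** Group means are anchored to the reported
  season endpoints (NH4: 3.11 -> 2.27 mg/kg rainy and 2.68 -> 1.59 dry;
  NO3: 0.33 -> 0.09 and 0.27 -> 0.06) with the intermediate treatments set
  from the reported percentage reductions — only in-study numbers are
  used.
* **Other soil/plant variables** follow monotone treatment trends in the
  reported directions (silt, SOC, DOC, TN, TP, AP, AK and biomass decline;
  sand and TK rise; pH, SM and clay carry no trend), with endpoint
  magnitudes chosen as field-plausible values for a dry-hot-valley arable
  topsoil. Within-group dispersions are not reported anywhere, so the
  plot-level noise CV is a free generator parameter: lognormal noise
  (concentrations are positive and right-skewed) with a default CV of 15%,
  a typical replicate-scale CV for soil chemical measurements. Soil
  texture closes exactly (clay is the remainder of 100% after sand and
  silt).
* **Communities.** Dirichlet-multinomial genus counts (total concentration
  200; library sizes negative-binomial around 10^4 reads) over
  season-specific genus pools: in the dry season every dominant AMF genus
  but *Diversispora* drops out, while nifH keeps *Bradyrhizobium* dominant
  and swaps its season-specific genera. Rainy-season composition drifts
  with erosion thickness through an exponent tilt of the mean profile —
  sharpening dominance for AMF (Shannon declines with erosion, tilt 0.75
  per 40 cm) and flattening it for nifH (Shannon rises, tilt 0.5) — while
  dry-season composition is treatment-independent. This reproduces the
  qualitative pattern the analysis is meant to detect: significant
  rainy-season PERMANOVA contrasts, non-significant dry-season ones.

What the generator does **not** emulate: real sequencing artefacts
(chimeras, contamination, rarefaction issues), spatial autocorrelation
among plots, true within-group variances or covariances between variables
beyond what the latent treatment/season structure induces, and any real
phylogeny (`community_tree()` is a seeded Yule tree and carries no signal).
Passing tests therefore demonstrate correctness and calibration of the
*methods* under known truth — not reproduction of the field study's
data-dependent numbers (group letters, PERMANOVA R² values, the SEM's R²),
which depend on unpublished raw data.

## The univariate chain

`screen_groups()` runs Shapiro-Wilk within groups and Brown-Forsythe
across groups. The homogeneity test is not named in the usual reporting of
this design, so the median-centred Levene form was chosen as the robust
default. `anova_lsd()` is a classical one-way ANOVA followed by
*unprotected* pairwise Fisher LSD comparisons on the pooled MSE with
`N - g` degrees of freedom, at `alpha = 0.05`, exactly as compact letter
displays in this literature imply — no multiplicity correction is applied,
so with 10 pairs the family-wise error is inflated; treat the letters as
descriptive. Letters come from the insert-and-absorb algorithm, which
guarantees that two groups share a letter exactly when their comparison is
non-significant. `reduction_rate()` is `100 * (control - treatment) /
control` on group means; note that percentages recomputed from 2-dp
printed means can differ in the second decimal from values computed on
unrounded data (27.01% vs a reported 27.19%, for instance) — the package
reproduces the arithmetic, not hidden precision.

## Beta diversity, NMDS and PERMANOVA

Bray-Curtis is computed on relative abundances by default, because library
sizes in the synthetic tables are sampling artefacts; a raw-count option
remains. Unweighted UniFrac is the unshared fraction of branch length
observed in either sample, with edge-wise presence accumulated in
postorder; entries are in [0, 1] and tested against exhaustive branch
enumeration and an independent implementation.

`nmds()` minimises Kruskal stress-1 by alternating pool-adjacent-violators
monotone regression (via `stats::isoreg` on the configuration distances
ordered by the input dissimilarities) with a Guttman-transform update.
Both half-steps are non-increasing in stress up to the moving
normalisation; a step-halving safeguard makes the recorded stress sequence
monotone non-increasing outright. Defaults: `k = 2`, 20 random starts plus
a classical-scaling start, 300 iterations maximum, convergence when the
stress decrease falls below 1e-7. The embedding is centred and rotated to
principal axes; its overall scale is arbitrary (stress-1 is
scale-invariant), so comparisons across runs should use normalised
distances or the stress value.

`permanova()` uses the distance decomposition of sums of squares
(equivalently, Gower-centred inner products) for a one-way design, with a
seeded label-permutation p-value under the `(hits + 1) / (n_perm + 1)`
convention — conservative and standard; 999 permutations by default.
An exhaustive mode enumerates all permutations for small n and is tested
against a brute-force oracle. Although the beta-diversity literature this
design follows mentions "analysis of similarities", the reported statistic
is R² — PERMANOVA/adonis output — so pairwise results are computed and
labelled as PERMANOVA. `pairwise_permanova()` runs all 10 treatment pairs.

## PLS path modelling

`fit_plspm()` follows the classical component-based (Lohmöller)
alternating algorithm with reflective (mode A) measurement — the
conventional default of the PLS-PM approach this design cites — and the
centroid inner scheme by default (factorial and path schemes are
available). Outer weights start at unity; iteration stops when the largest
outer-weight change drops below 1e-6 (300-iteration cap, error on
non-convergence). Path coefficients are per-equation least squares of each
standardized endogenous latent score on its parents, so a single-indicator
model is *exactly* standardized OLS — a property the tests assert to
1e-10. Sign indeterminacy is resolved by forcing each latent to load
positively on its dominant indicator, which keeps bootstrap aggregation
sign-stable. `bootstrap_paths()` resamples rows with replacement
(percentile 95% CIs; degenerate resamples skipped and counted), and
`total_effects()` sums coefficient products over all directed paths by
matrix powers until nilpotency.

The default structural model (`mineral_n_path_spec()`) uses erosion
thickness (cm) and the season dummy as single-indicator exogenous blocks;
TN alone; carbon as {SOC, DOC}; mineral nitrogen as {NH4, NO3}. The study
design does not state what measures the community constructs, so the AMF
and nifH blocks default to a dominant-genus relative-abundance summary
plus Shannon diversity — one evenness-sensitive and one
diversity-sensitive indicator per community — and are overridable via a
YAML model file (`read_path_spec()`). Note that with the generator's
strong seasonal turnover the AMF latent is nearly collinear with season,
so those two paths trade off and carry wide bootstrap intervals; that is a
property of the synthetic conditions, not of the estimator.

## Verification design and problem sizes

The test suite separates three kinds of evidence, with sizes chosen to
keep the default run in the minutes range:

* **Exactness**: the design-table values (12.12, 7.34, 2.69 and 7.88 cm)
  by both the closed form and the simulator; closed-form/simulator
  equivalence to 1e-9 cm over ~100 profile/rate/year settings;
  single-indicator PLS vs OLS to 1e-10; distances against hand arithmetic,
  enumeration oracles and independent implementations.
* **Calibration**: ANOVA type-I error at 4000 null simulations (g = 5,
  n = 10) and PERMANOVA at 1000 null datasets x 199 permutations, both
  required to sit in 5% ± 1%; exhaustive-permutation PERMANOVA equality
  with a brute-force oracle at n = 6; bootstrap CI coverage pooled over
  the 10 paths of a known latent model x 200 seeds (n = 500, B = 199),
  required to sit in 95% ± 2%. Coverage is assessed on single-indicator
  blocks so the true population coefficients are exactly the generating
  ones.
* **Recovery**: path coefficients on a two-indicator latent model
  (n = 500) are compared with truth through the mean estimate over 20
  independent datasets, because a single dataset's sampling error for
  collinear parents (~0.05 SE) is as large as the tolerance — averaging
  isolates systematic bias, which is the estimator property under test.
  Indicators use loadings of 0.98; composite reliability below ~0.95
  attenuates PLS path estimates noticeably (a known property of composite
  scores), which is a fact about measurement error, not a defect of the
  fitting algorithm.

## Known limitations

The mixing model ignores interannual variation in erosion rate and bulk
density differences between horizons; the construction plan computes
geometry only (no machinery or logistics). The univariate chain analyses
seasons separately (no season x treatment interaction model, matching the
reported design) and the LSD letters are uncorrected. NMDS minimises
stress locally per start; multi-start mitigates but cannot guarantee the
global optimum. PERMANOVA is one-way only. PLS-PM is component-based:
with few, noisy indicators its path estimates are attenuated relative to
covariance-based SEM, and no global fit indices are provided.
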