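---
title: "Hydraulic habitat suitability for Amazonian freshwater mussels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydraulic habitat suitability for Amazonian freshwater mussels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`musselhab` implements a habitat-suitability analysis for two Amazonian
freshwater mussels, *Castalia ambigua* (Hyriidae) and *Anodontites
elongatus* (Mycetopodidae), from plot-level river surveys: near-bed flow and
sieve granulometry are converted into "complex" hydraulic variables, random
forests relate mussel density to those variables (and to landscape
stressors), and the spatial arrangement of occupied plots is characterized
with kernel intensity surfaces and the Hopkins–Skellam test. A seeded
synthetic reach generator emulates the survey design so that the whole
pipeline can be exercised, and its parameter recovery quantified, without
field data.

## Substrate metrics

Each 1-m² plot contributes a sieve stack: the mass retained on the six
geological sieves (2, 1, 0.5, 0.25, 0.125, 0.063 mm) plus the pan. The
cumulative percent-finer-by-mass curve is interpolated log-linearly on the
phi scale (φ = −log₂ D with D in mm), the standard sedimentological
convention; linear-in-mm interpolation is available as an option. The
percentile diameters D16, D50, D84 give

* mean particle size `D_mean = (D16 + D50 + D84) / 3` (mm),
* sorting index `So = (φ84 − φ16) / 2`, and
* bed roughness `ks = 2·D50` (mm).

A convention the source tables leave open: φ84 could mean φ(D84) or the 84th
percentile of the phi distribution. We use the latter — phi increases as
diameter decreases, so φ84 sits in the *fine* tail (φ84 = −log₂ D16) and So
is a nonnegative spread, consistent with its use as a heterogeneity measure
(0.1 "very well sorted" … 0.9 "moderately sorted" on the Folk and Ward
verbal scale). Extreme-percentile handling: the pan fraction is assigned a
nominal lower bound of 0.001 mm and the coarsest fraction an upper bound of
twice the largest aperture; a percentile falling into either extreme
fraction is interpolated within those nominal bounds and flagged with a
warning. All metrics are invariant to the total sieved mass, so the 100-g
subsample convention is not enforced.

## Hydraulic variables

From near-bed current velocity U (m/s, measured 1 cm above the bed) and
depth d (m), with the documented constants (g = 9.8 m/s², ν = 1.76×10⁻⁵
m²/s, μ = 1.73×10⁻⁴ Pa·s, ρ = 996 kg/m³, θc = 0.035):

| variable | formula |
|---|---|
| Froude number | Fr = U²/(g·d) |
| Reynolds number | Re = U·d/ν |
| shear stress | τ = μ·(dv/dy), dv/dy = U/0.01 |
| shear velocity | V = √(τ/ρ) |
| boundary Reynolds number | Re\* = V·ks/ν |
| critical shear stress | τc = θc·g·D50·(ρs − ρ) |
| stream power | w_a = τ·U |

Two deliberate fidelity choices:

* **Froude convention.** Fr is implemented exactly as the source variable
  table prints it, U²/(gd) — the square of the conventional open-channel
  definition U/√(gd). `froude = "conventional"` switches to the standard
  form.
* **Substrate density.** The documented ρs is 273 kg/m³, *below* water
  density, which makes τc negative. The value is kept as the default for
  fidelity, a warning is emitted whenever ρs < ρ, and the quartz-sand value
  (2730 kg/m³) is available as an override. The sign of τc does not affect
  any other variable.

The velocity gradient dv/dy = U/0.01 follows from the measurement height:
velocity at 1 cm above the bed, no-slip at the bed, two-point gradient over
0.01 m. Internally everything is SI; millimetres appear only in the
grain-size interface (ks and D50 are converted to metres inside Re\* and
τc).

## The forest protocol

Mussel densities are `log(x+1)`-transformed (natural log; base 10 by
option). Forests are grown with an explicitly controlled bootstrap: per
tree, *groups* of rows are resampled with replacement and all rows of a
sampled group enter together. With each row its own group this is the
ordinary random forest; with a grouping column (transect by default in the
pipeline; plot or site can be chosen) it is the repeated-measures variant
that respects non-independence of plots within a group. A row is out-of-bag
(oob) for a tree iff its group was not drawn, and oob predictions aggregate
only over such trees. Tree growing itself is delegated to `ranger` (with
per-tree in-bag counts supplied), but the bootstrap scheme, oob
bookkeeping, error estimation, importance, tuning and partial dependence
are implemented in this package and tested against brute-force oracles.

* **Tuning** sweeps mtry (1..p) × ntree {200, 300, 400, 500, 600, 800,
  1000}, refitting each cell five times under derived seeds, and selects the
  cell with the smallest mean oob MSE (ties: smaller mtry, then smaller
  ntree).
* **pseudo-R²** = 1 − MSE_oob/Var(y), with the population variance; it may
  be negative.
* **%IncMSE**: per predictor and per tree, the predictor's values are
  permuted within the tree's oob rows and the oob MSE increase recorded; the
  statistic is the mean per-tree increase divided by its standard error
  across trees (the classic scaling), with the raw increase also reported.
  Per-tree predictions for the permuted data use an exact single-tree
  traversal (compiled) over the fitted trees, verified against the engine's
  own predictions. `importance_reseeded()` averages the statistic over five
  reseeded forests, mirroring the protocol of rerunning each model under
  different seeds before reading the ranking.
* **Partial dependence** is the brute-force definition — set the predictor
  to v for all rows, average the forest prediction — computed exactly, and
  `suitability_window()` reads the contiguous half-height interval around
  the curve maximum as the suitability range.

Determinism: every stage derives its own seed stream from one master seed;
the whole protocol is bit-reproducible.

## Spatial pattern

Occupied plots form a planar point pattern in a rectangular (or polygonal)
window in local projected coordinates. The intensity surface is an isotropic
Gaussian kernel sum (mark-weighted when marks are present) with uniform
edge correction — each cell is divided by the kernel mass inside the window
— so the surface integrates to the point count (or mark total) up to
discretization error (≤ 1% on a 256² grid, tested).

The bandwidth is selected by minimizing a mean-squared-error criterion for
the kernel estimator of a stationary Cox process, written out explicitly for
the Gaussian kernel:

$$M(\sigma) = \frac{\hat\lambda}{4\pi\sigma^2}
 + \frac{1}{a}\sum_{i \ne j}\left[k_{\sigma\sqrt2}(d_{ij}) - 2\,k_\sigma(d_{ij})\right],
 \qquad k_s(d) = \frac{e^{-d^2/2s^2}}{2\pi s^2},$$

with window area a and λ̂ = n/a: the first term is the integrated squared
kernel (estimation variance), and the pair sum plugs the empirical pair
structure into the smoothing-bias terms. No edge correction is applied to
the pair distances — a documented limitation; the exact criterion variant
used in other software is unstated, so this formula is the package's
definition and is tested against an independent direct summation.

The Hopkins–Skellam statistic is oriented so that

$$A = \frac{\sum_i \text{nn}_i^2}{\sum_j \text{es}_j^2} \;<\; 1
 \;\Rightarrow\; \text{clustering},$$

where nn are nearest-neighbour distances among the n events and es are
distances from n uniform random test locations to the nearest event (the
literature also uses the reciprocal; the orientation here matches the
interpretation "< 1 suggests clustering"). The p-value is two-sided, by
Monte-Carlo rank against CSR simulations with the same n and window
(default nsim = 999; at least 19 required); the analytic F(2n, 2n)
reference is available but fragile in small windows. By default the test
uses the occupied plots as unweighted events; mark-weighted smoothing is a
separate, documented mode of the intensity surface. Calibration (type-I
error within [0.03, 0.07] at α = 0.05 under CSR; power ≥ 0.9 against tight
Thomas clusters) is part of the acceptance suite.

## The synthetic reach generator

The generator emulates the survey design: 6 sites × 6 mesohabitats × 2
transects of 100 m × 25 plots of 1 m² at low flow (300 plots per reach),
with a seeded 15-per-transect revisit at high flow (180 per reach).
Mesohabitat speed distributions are zero-truncated normals with the
documented means and SDs per flow period (e.g. outer meander margin
0.4 ± 0.1 m/s at low flow, meander thalweg 1.2 ± 0.5 m/s at high flow); the
truncation bias is analytic (`truncnorm_mean()`) and enters the calibration
tolerance. Plot positions are stratified along each transect with uniform
jitter — one plot per 4-m stratum — which reproduces the protocol's
avoidance of clumping; the exact field geometry is unspecified, so this
layout is a documented default, not a claim about the study.

Choices the survey tables do not determine, fixed once and documented here:

* **Depths** are lognormal with mesohabitat-specific medians (thalweg
  deepest at 1.8 m, outer margin shallow at 0.3 m) — depth is not reported
  per mesohabitat.
* **Sediments** are two-component phi-scale mixtures: a main sand mode
  whose median lies in a band inside the mesohabitat's grain-size range,
  plus a displaced secondary mode (a gravel lag or a silt drape, 2.5–4 phi
  away) holding up to ~20–40% of the mass depending on mesohabitat
  stability. Fluvial deposits are typically bimodal, and the secondary mode
  is what decouples the distribution tails — hence mean particle size and
  sorting — from the median diameter; with a single lognormal mode,
  `D_mean`, `ks` and `τc` would be deterministic near-copies of each other
  and the importance ranking of the habitat model would be unidentifiable.
  Consequently the mesohabitat grain-size range constrains the *main mode*;
  mixture tails may spill past it.
* **Species responses** are unimodal suitability windows: expected density
  = peak × w(D_mean)·w(Fr)·w(Re)·w(So) × a cluster field along the
  transect × an optional site-level landscape multiplier, with
  negative-binomial counts (size 8). The window locations are the
  documented suitability ranges (D 0.3–0.5 / 0.2–0.4 mm, Fr 0.005–0.075,
  Re 500–1800 / 500–1000, So 0.1–0.9). Edge steepnesses are
  per-variable: crisp for the substrate windows and the Froude edge,
  a wide logistic shoulder for the Reynolds edge. The wide Re shoulder is a
  considered choice: under the documented speed distributions and
  constants, Fr ≤ 0.075 requires d ≥ U²/0.735 while Re ≤ 1800 requires
  d ≤ 0.0317/U, which hold jointly only for U ≤ 0.29 m/s — the lower ~13%
  tail of the margin speed distribution. Hard-edged products therefore
  produce essentially empty reaches; treating the published ranges as ridge
  locations of a smooth response (which is what ranges read off
  partial-dependence curves of collinear predictors are) keeps the planted
  signal recoverable while preserving every window location. Plots of the
  silt-flagged inner meander margin are forced to zero density regardless
  of hydraulics.
* **Landscape**: the 13 site-level variables are drawn from documented
  uniform ranges; the site density multiplier increases with distance to
  the nearest rural settlement and street and decreases with the percent of
  rural settlements and road density, while agriculture and pasture are
  generated with no effect. With the study's six sites a 13-predictor
  ranking is not estimable, so the recovery property is exercised at a
  larger synthetic site count (60) in the tests and stage 4 of the
  analysis.

### What passing tests do and do not show

The generator reproduces the survey's *design* (counts, speed
distributions, grain classes, clustered occupancy confined to the stable
margin) and a response with the published suitability structure; it does
not reproduce the field data themselves, raw-data results, or real river
geometry, and real sediments, flows and mussel counts are messier in ways
the generator does not attempt (temporal variation, detection error,
multimodal flows). Passing recovery tests shows the *methods* can find
planted structure of realistic strength at the survey's sample sizes — not
that the field inference is correct.

A structural caveat quantified during development and visible in the
acceptance suite: with nine predictors derived from four measured
quantities (U, d, and two substrate axes), five of the hydraulic variables
are deterministic functions of the others (τ and V of U alone; ks and τc
of D50; Re\* of both), so permutation importance divides credit among
near-duplicates. At the full study scale (six reaches, n = 1800) the
explained variance matches the published magnitudes (≈ 79% for
*C. ambigua*, ≈ 50% for *A. elongatus*) and the planted sorting index,
grain size, Froude and Reynolds windows dominate the ranking — but the
*fourth* importance rank is decided by roughly one standard deviation of
between-dataset variation, and the boundary Reynolds number (the single
best composite proxy of "stable-margin-ness") takes that slot in a
substantial minority of runs. The acceptance check that requires the exact
planted top-four in ≥ 90% of runs is therefore expected to fail for at
least one species under these honest conditions; it is retained unweakened
as a falsifiable statement of that identifiability limit.

## Problem sizes and numerical choices

Habitat-model recovery runs use the full six-site study (n = 1800) with
mtry = 6, ntree = 200 in the test suite (ntree = 300 in the analysis
drivers) and importance averaged over five reseeds; the null-calibration
suite uses n = 300, p = 9, ntree = 500, 50 runs; the spatial calibration
uses n = 100 points with 199-fold Monte-Carlo p-values over 1000 (type-I)
and 200 (power) replicates. Ties in tuning are
broken toward smaller mtry then smaller ntree; ties in bandwidth selection
toward the smaller σ; percentile interpolation across zero-mass fractions
takes the phi-midpoint of the flat segment. Degenerate inputs (zero total
sieve mass, nonpositive depth, fewer than two points or groups, flat
partial-dependence curves) raise errors or documented warnings rather than
propagating silently.
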