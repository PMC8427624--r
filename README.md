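# musselhab

Habitat-suitability analysis for Amazonian freshwater mussels — *Castalia
ambigua* (Hyriidae) and *Anodontites elongatus* (Mycetopodidae) — from
plot-level river surveys, for freshwater ecologists and fluvial
biogeomorphologists.

Mussel density in lowland rivers is governed less by simple flow summaries
than by *complex* near-bed hydraulic variables and substrate texture. From
per-plot near-bed velocity U (m/s, 1 cm above the bed), depth d (m) and a
six-sieve granulometric stack, the package computes:

* substrate: percentile diameters D16/D50/D84, mean particle size
  `D = (D16 + D50 + D84)/3`, sorting index `So = (φ84 − φ16)/2`
  (φ = −log₂ D[mm]), bed roughness `ks = 2·D50`;
* hydraulics: Froude number `Fr = U²/(gd)`, Reynolds number `Re = Ud/ν`,
  shear stress `τ = μ·U/0.01`, shear velocity `V = √(τ/ρ)`, boundary
  Reynolds number `Re* = V·ks/ν`, critical shear stress
  `τc = θc·g·D50·(ρs − ρ)`, and stream power `w_a = τ·U` at high flow.

Around these it implements a random-forest protocol — log(x+1) density
transform, out-of-bag mtry/ntree tuning with five reseeds, a
repeated-measures (group-bootstrap) variant, permutation importance
(%IncMSE) and exact partial dependence with suitability-window read-off —
plus spatial pattern analysis of occupied plots (Gaussian kernel intensity
with edge correction, mean-squared-error bandwidth selection, and the
Hopkins–Skellam clustering test, A < 1 ⇒ clustering). A seeded synthetic
reach generator emulates the survey design (6 sites × 6 mesohabitats × 2
transects × 25 one-m² plots at low flow; 15 per transect revisited at high
flow) so the whole pipeline is testable without field data. See the methods
vignette (`vignettes/methods.Rmd`) for models, assumptions and parameter
choices.

## Worked example

The analysis workflow lives in `analysis/01_simulate.R` …
`05_pointpattern.R`; run them in order from the repository root. Stage 1
simulates the six-site study (1800 plots) and stages 2–3 compute the metric
table and fit the repeated-measures hydraulic forest per species. Stage 3
prints, for *C. ambigua*:

```
== castalia: oob MSE 0.048, pseudo-R2 78.8% ==
 predictor pct_inc_mse rank
        So    40.16076    1
    D_mean    18.50877    2
        Fr    17.73693    3
        Re    17.21420    4
   Re_star    14.78175    5
       tau    12.30950    6
         V    11.70204    7
     tau_c    11.00025    8
        ks    10.35537    9
  suitability window for So      : 0.3617 - 0.654
  suitability window for D_mean  : 0.3091 - 0.5058
```

Reading this: the forest explains ~79% of the out-of-bag variance in
transformed density; the four planted drivers of the synthetic study —
sorting index, mean particle size, Froude and Reynolds numbers — head the
permutation-importance ranking, ahead of their correlated hydraulic
proxies; and the half-height window of the mean-particle-size
partial-dependence curve (0.31–0.51 mm) recovers the species' planted
medium-sand suitability range (0.3–0.5 mm). Stage 4 shows the four
riparian-buffer urbanization stressors (distance to rural settlement and
street, percent rural settlement, road density) dominating the landscape
model, and stage 5 maps kernel density and tests the occupied-plot pattern
(A < 1: clustered within the stable outer meander margin).

Small stage outputs are kept under `results/`; the large per-plot tables
(`plots.csv`, `metrics.csv`) are regenerated by stages 1–2.

Programmatic use mirrors the scripts:

```r
library(musselhab)
study <- simulate_study(default_design(sites = 6), seed = 1)
h <- hydraulic_table(study$plots, period = "low")
h$response <- transform_density(h$dens_castalia)
h$tr <- paste(h$site, h$mesohabitat, h$transect)
imp <- importance_reseeded(h, "response",
         c("D_mean","So","ks","Fr","Re","Re_star","V","tau","tau_c"),
         mtry = 6, ntree = 300, seed = 1, groups = h$tr)
head(imp, 4)
```

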