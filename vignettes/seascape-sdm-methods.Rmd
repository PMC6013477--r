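---
title: "Modelling fish abundance and biomass from seafloor terrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fish abundance and biomass from seafloor terrain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seascapeSDM)
```

## The modelling problem

Demersal fishes associate with seafloor structure, and those associations
often differ between life stages: juveniles may hold to complex, shallow
refuges while large adults range over deeper, flatter ground. seascapeSDM
models two complementary responses at video survey sites --

* **relative abundance**: MaxN, the maximum number of individuals of a
  species visible in any single frame of a baited-video deployment, a
  conservative count that cannot double-count fish; and
* **individual biomass**: per-fish mass in grams, computed from stereo
  fork-length measurements through the species' length-weight power law
  `W = a L^b` (sexes averaged when the fish cannot be sexed on video),

as smooth functions of six terrain covariates derived from a bathymetry
grid, and then maps the fitted surfaces back over the full raster domain to
score juvenile and adult "hotspots" shared across species.

## Terrain covariates

From a regular bathymetry grid (metres, negative below datum) the package
derives five covariates, giving six layers in all:

| layer | meaning | construction |
|---|---|---|
| `bathymetry` | depth | input grid |
| `slope` | steepness, % rise | Horn 8-neighbour gradient, `100 sqrt(p^2+q^2)` |
| `eastness` | east-west component of the downhill direction | `sin(aspect)` |
| `northness` | north-south component | `cos(aspect)` |
| `range10` | coarse relief | focal max − min in a 10 × 10-cell window |
| `curvature` | convexity | Zevenbergen-Thorne combined curvature, `-2(D+E)·100` |

Numerical conventions, chosen once and fixed: flat cells (zero gradient)
carry aspect code −1 and neutral eastness/northness 0; cells whose 3 × 3
neighbourhood contains missing data are missing in slope, aspect and
curvature (conservative derivatives), while the relief window uses whatever
valid cells it holds (permissive relief) and truncates at grid edges; all
six layers share the union nodata mask. On a 4 m grid the default relief
window covers 40 m × 40 m = 1600 m² of seabed. Aspect is the compass
direction the slope *faces* (downhill), 0° = north, 90° = east.

## Response models and full-subsets selection

MaxN counts contain many zeros and are overdispersed, so abundance is
modelled with a negative binomial GAM (log link, dispersion estimated by
maximum likelihood); individual biomass is strictly positive and
right-skewed, so it uses a gamma GAM (log link). Zeros stay in the
abundance data; biomass models see only measured individuals. Every
predictor enters as a penalized thin-plate smooth with basis dimension
`k = 4`, capping each term at 3 effective degrees of freedom -- deliberately
conservative given a few hundred sites.

Rather than stepwise selection, the package fits **every admissible subset**
of the six covariates with at most four terms (plus the intercept-only
null). Admissibility is screened on collinearity: pairs with
|Pearson r| > 0.28 (the conventional conservative threshold in the
full-subsets ecology literature; configurable) never co-occur. Models are
ranked by small-sample-corrected AIC,

$$\mathrm{AICc} = -2\ell + 2k + \frac{2k(k+1)}{n-k-1},$$

where `k` counts total effective degrees of freedom including the intercept
and one dispersion/scale parameter -- a deliberate choice that keeps
negative binomial and gamma fits comparable. Akaike weights
`w_i = exp(-Δ_i/2) / Σ exp(-Δ_j/2)` quantify relative support; per-covariate
importance is the summed weight of all models containing that covariate.
The best model is the highest-weight model among those with ΔAICc < 2
(equivalent to lowest AICc under the standard weight formula; exact ties
break to the smaller subset, then lexicographically, so selection is
deterministic). Reported fit is a deviance-based adjusted R²,
`1 − (1 − R²_dev)(n−1)/(n−edf)` with `R²_dev = 1 − D_res/D_null`; the `df`
column reports total effective df including the dispersion parameter.
Individual non-convergent candidate fits are dropped with a warning rather
than aborting the run.

## Validation

* **Repeated k-fold cross-validation** (defaults 5 folds × 50 repetitions):
  the *selected* predictor set is refitted on each training split -- no
  re-selection inside folds -- and held-out predictions are pooled per
  repetition. Error is reported as normalized RMSE,
  `100 · RMSE / (max(y) − min(y))`, the error as a percentage of the
  observed response range; a constant response makes this undefined and is
  an error. Folds differ in size by at most one and the partition sequence
  is reproducible from the seed.
* **Geographically weighted regression** of observed on predicted values,
  with bisquare kernel weights and an adaptive bandwidth (distance to the
  k-th nearest neighbour, k chosen by leave-one-out CV when not given),
  exposes spatial nonstationarity in model fit. Local standardized
  residuals divide raw local residuals by the global residual SD. For
  biomass, records are aggregated to site means first so coordinates are
  distinct.
* **Moran's I** on the standardized GWR residuals (k = 8 nearest
  neighbours, row-standardized, configurable) tests for residual spatial
  autocorrelation; inference uses the normality approximation
  (`E[I] = −1/(n−1)`, two-sided z test), matching the common
  reporting of z-scores and p-values. A non-significant I indicates the
  terrain covariates absorbed the spatial structure.

## Spatial prediction and hotspots

Best models are predicted over every valid raster cell on the response
scale. Prediction is *constrained*: covariates beyond the training envelope
are clamped to the training minimum/maximum, so smooths are never
extrapolated (a masking mode that drops such cells is available instead).
Predicted biomass is reclassified at a per-species cutoff (grams,
supplied in configuration as a biological parameter; cells exactly at the
cutoff count as mature -- an arbitrary but fixed rule). Summing the binary
maps over species gives integer hotspot scores from 0 to S; with three
species a juvenile or adult hotspot peaks at 3, and the juvenile and mature
scores always add to S because each species' cell is exactly one class.
Abundance rasters are summed directly (best-model predictions, not
model-averaged) into a cumulative abundance surface.

## What the synthetic generator emulates

Because no field data ship with the package, `generate_bathymetry()`,
`sample_sites()` and `simulate_fish()` reproduce the statistical structure
the analysis assumes:

* a shallow embayment deepening from −5 m at the southern (coastal) edge to
  −40 m offshore, crossed by discontinuous shore-parallel ridges (Gaussian
  cross-shore profile, sinusoidal along-shore modulation, pointwise maximum
  across ridges so relief never exceeds the configured amplitude) plus
  3 × 3-smoothed Gaussian noise (default SD 0.5 m) standing in for reef
  micro-relief. The native resolution default is a 4 m cell over a
  7 km × 10 km domain, with 217 sites at least 400 m apart stratified over
  four equal-width depth bins -- a realistic single-embayment survey;
* MaxN drawn from a negative binomial (log link) whose linear predictor
  combines named effect curves (linear, quadratic, saturating, threshold)
  of standardized covariates, so zeros arise from the count distribution
  itself; and per-individual gamma biomass with fork lengths back-computed
  through the inverse length-weight law.

The default truth for the first synthetic species drives abundance through
depth, eastness and northness. That choice is deliberate: in ridge terrain,
relief measures (slope, `range10`) are intrinsically correlated with each
other and with depth, so a planted truth containing two of them would
sometimes be screened out by the |r| > 0.28 rule and no selection method
could recover it; depth and the two aspect components stay mutually
identifiable. Length-weight coefficients and juvenile/adult cutoffs in the
default truths are synthetic placeholders of realistic magnitude
(`W ≈ 1e-5 L^3`), treated as data throughout -- real analyses must supply
published values.

What passing tests on this generator do **not** show: the generator has no
habitat classes (seagrass, sand), no bait-plume or behavioural
interactions between nearby deployments, no measurement error in lengths,
and its smooth effects are low-dimensional. Good recovery here demonstrates
the machinery is correct, not that any real system is this well behaved.

## Problem sizes and numerical choices

The package's own test and example runs use compact problem sizes chosen
for interactive turnaround: structure-recovery and cross-validation
experiments use 200-site surveys on a 1 km × 1.6 km seascape at 4 m cells
with proportionally reduced site spacing (40 m), and the default pipeline
configuration grids the 7 km × 10 km domain at 20 m with 200 sites at
400 m spacing -- the terrain derivatives are scale-aware, so nothing but
runtime changes at 4 m. Other fixed choices: ESRI ASCII grid is the raster
interchange format (plain text, nodata −9999, cell-centre registration,
row 1 northernmost); AICc requires `n > k + 1`; the GWR bandwidth search
grid spans 15-99% of sites; and all randomness flows from explicit integer
seeds recorded in outputs, making every pipeline rerun byte-identical.

## Limitations

Selection inference is conditional on the screened candidate set; summed
Akaike weights measure relative, not absolute, importance. The GWR
diagnostic regresses observed on predicted and is exploratory -- it does not
correct the models. Predictions are clamped, so maps are conservative
outside the sampled covariate envelope. Biomass models ignore unmeasured
individuals beyond those at MaxN, and sites are point-sampled from the
covariate rasters (the neighbourhood is already encoded in `range10`)
rather than window-averaged.
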