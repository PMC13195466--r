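---
title: "Estimating prescribed-fire PM2.5 with zero-out attribution and data fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating prescribed-fire PM2.5 with zero-out attribution and data fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfsmoke)
```

## The problem

Prescribed fire (PF) — intentional, controlled burning used to reduce
wildfire fuels — is a major source of fine particulate matter (PM2.5) in
regions where it is practiced intensively. Quantifying how much of ambient
PM2.5, and of its chemical components (elemental carbon EC, organic carbon
OC, nitrate, sulfate), is attributable to PF requires combining three
imperfect information sources:

* **fire activity records** — satellite fire detections see large burns
  everywhere but miss small ones and over-report area; state burn permits
  record area accurately but only where reporting is mandatory;
* **chemical-transport-model (CTM) simulations** — spatially and temporally
  complete, source-resolving, but biased;
* **monitor observations** — accurate but sparse in space, and speciation
  monitors typically sample only one day in three.

`pfsmoke` implements the full estimation chain as composable stages, and —
because CTM runs on real emission inventories are far outside desk scale —
ships a synthetic-study generator that emulates all three sources with a
known ground truth, so that every stage's claims are testable.

## The estimation chain

**Burned-area calibration.** Satellite and permit burned areas are summed on
(grid cell, day) keys and matched (`match_pairs()`); a least-squares
regression of permit on satellite area *through the origin* (`fit_scaling()`)
yields a single scaling factor applied to all satellite areas
(`apply_calibration()`). Keys with a positive satellite total and no permit
record are retained with permit area 0 — discarding them would bias the
slope upward. The regression is through the origin because the correction is
applied as a pure rescale; an intercept is available as an option.

**Emissions.** Each event's fuel consumed is area × fuel load × consumption
fraction, and species emission is fuel consumed × emission factor (g/kg)
(`compute_emissions()`). A single uniform fuel type is assumed; defaults
(14.7 t/acre × 0.95 × 50 g/kg PM2.5) give ≈ 0.7 tons of PM2.5 per acre
burned, with component factors in the proportions EC 13%, OC 46%, NO3 2%,
SO4 4% of PM2.5 mass. These are placeholders with the right aggregate
intensity, not a fuel-chemistry database.

**Zero-out attribution.** Two simulations are paired: baseline (all
emissions) and a rerun with PF emissions removed. The PF-attributable field
is their pointwise difference (`pf_delta()`), kept unclamped: negative
deltas are physically possible under nonlinear chemistry, and clamping
would silently break the identity "component deltas sum to the total
delta". A floor-at-zero option exists at the aggregation stage instead.

**Data fusion of totals.** `fuse_total()` corrects the simulated total-PM2.5
field toward observations in two steps, per day:

1. a polynomial mapping simulated → observed concentration is fit over
   collocated (monitor, day) pairs and applied to the whole field. Days
   with fewer than `min_pairs_per_day = 5` pairs fall back to a pooled fit
   over all days. Beyond the concentration range of the fitting data the
   polynomial continues *linearly* (its tangent at the range endpoint), so
   plume cells hotter than any monitored value are rescaled, never
   extrapolated polynomially;
2. residual ratios obs/corrected at each monitor are interpolated over the
   grid as log-ratios by inverse-distance weighting (power 2) tapering to
   ratio 1 at 300 km, and multiplied in. Near a monitor the field tracks
   that monitor almost exactly; far from all monitors it stays model-shaped.

The default polynomial degree is 1. We originally used degree 2, but with
a few dozen pairs per day the quadratic's tangent extension repeatedly
over-amplified held-out plume cells (factors up to ~5) and made
site-held-out cross-validated RMSE *worse* than the raw model on some
realizations; degree 1 improved held-out RMSE on every realization we
probed. The degree remains configurable for denser networks.

**PF impact fusion.** The observation-adjusted PF impact multiplies the
simulated delta by the fused/simulated concentration ratio,
`fuse_pf_total()`. Where the denominator floor (0.01 µg/m³) and the
multiplier cap (10) are inactive, this preserves the simulated *PF
fraction* of total mass exactly — fusion rescales amplitude, it does not
re-apportion sources.

**Species fusion via ratios.** Components are never fused directly:
the fused EC + OC + NO3 + SO4 + OTHER would not sum to the fused total, and
1-in-3-day speciation sampling would inject temporal aliasing.
`fuse_species_ratios()` instead corrects simulated species-to-total
*ratios* with observed ratios (same-sampler totals), interpolating the
log-corrections linearly in time between a site's sampling days (held
constant beyond endpoints) and spatially by the same tapered IDW. Fused
ratios are clipped to [0, 1], OTHER is defined by subtraction (clipped at
0), and the vector is renormalized to sum exactly 1 — so fused component
masses always sum to the fused total, by construction. Component PF
impacts then follow the same ratio equation (`fuse_pf_species()`).

**Evaluation.** `compute_stats()` reports MB, RMSE, NMB, NME, MNB, MNE and
R² (MNB/MNE over pairs with observation ≥ 1 µg/m³, to avoid near-zero
division). `kfold_cv()` partitions *sites* — not observations — into k
folds, refits the fusion without each fold, and scores it at the withheld
sites; observation-level folds would leak through spatial interpolation.
In-sample fused-vs-observation statistics are near-perfect by construction
(the residual IDW step interpolates the training monitors), so benchmark
flags and reported fusion skill use the held-out statistics.
`count_pf_exceeds_obs()` implements the plausibility diagnostic: an
estimated PF contribution exceeding the collocated observed *total* PM2.5
is unrealistic, and fusion should reduce the count of such cell-days.

**Aggregation.** `compute_coverage_weights()` computes exact polygon-cell
coverage fractions by Sutherland–Hodgman rectangle clipping and the
shoelace formula (planar geometry in grid coordinates; a projection layer
would precede this for geographic data). `weighted_daily_mean()`,
`period_summary()` (mean, sample SD, median by year × season),
`pf_share()` (ratio of period means × 100) and `exceedance_stats()`
(fraction of grid-cell-days ≥ threshold; count of days whose regional mean
exceeds it) produce the reporting quantities. Seasons follow the burning
calendar: JFMA (extensive), MJJAS (least active), OND (moderate).

## What the synthetic generator emulates

`synthetic_study()` draws every input with a known truth:

* **Burn truth** — event counts Poisson around 12/day; dates drawn with
  seasonal area shares 54.1% / 22.1% / 23.8% (JFMA/MJJAS/OND); areas
  log-normal (meanlog 3.5, sdlog 1.2 — median ≈ 33 acres, heavy right
  tail); 84% on private land.
* **Degraded records** — satellite: events < 1.18 acres invisible, 30% of
  the rest missed, areas divided by 0.66 (systematic over-reporting);
  permits: 90% coverage, areas exact.
* **Concentration fields** — a toy linear dispersion model: each source's
  emitted mass spreads over the grid as an isotropic Gaussian (scale 18 km)
  displaced by a per-day random wind offset (SD 12 km), normalized so mass
  is conserved, and converted to surface concentration by a box factor
  (mixing height 1000 m) times a retention factor 0.12 representing
  ventilation and deposition losses over the 24 h average. The total field
  is the exact sum of the five component fields. Background components sum
  to ≈ 10 µg/m³ with a smooth spatial pattern and a seasonal day factor.
  These scales put domain-mean PF-PM2.5 near 0.5 µg/m³ and plume maxima in
  the tens of µg/m³ — the magnitudes the method is meant to operate on.
* **Model error** — the "model" pair is the truth pair with (i) per-species
  amplitude biases (total ×0.80, EC ×0.71, OC ×1.42, NO3 ×0.90, SO4 ×0.79),
  (ii) PF plumes displaced by a constant 24 km wind error, and (iii) a
  per-day lognormal amplitude error (SD 0.15) common to all species.
  The second and third components matter: a model that is *only* a scalar
  multiple of truth is perfectly correlated with it, so no fusion could
  improve its R², and its PF estimates could never exceed observed totals —
  the two behaviors the evaluation stage exists to measure. Plume
  misplacement and day-specific meteorological error are the canonical CTM
  error modes that produce both.
* **Observations** — truth at the site cell × (1 + ε), ε ~ N(0, 0.10),
  truncated at 0; 30 daily total-PM sites (3 flagged near-road and excluded
  from fusion), 8 speciation sites on 1-in-3-day schedules.

The default domain is a 30 × 30 grid of 12 km cells and 120 daily slices
spread across calendar 2021 (every third day), so all three burning seasons
are represented at desk scale; 120 *consecutive* days could never leave the
January–April season. All generators are bit-reproducible from one global
seed via fixed per-stage sub-seeds.

What the generator does **not** emulate: chemistry and deposition,
meteorological transport structure (plumes are Gaussian blobs), spatially
correlated model error, monitor siting bias, reporting gaps, or satellite
false detections (no commission errors — every satellite event descends
from a truth event). Passing tests therefore demonstrate the estimator's
internal consistency and its behavior under known, controlled error
structure — not performance on real networks.

## Numerical choices

* Every denominator in the ratio equations is floored at 0.01 µg/m³, and
  every multiplicative correction capped at 10 (and 1/10); near-zero
  simulated concentrations otherwise make Eq-style ratios explode.
* Fused concentration fields are floored at 0.01 µg/m³.
* IDW uses distance floored at 1 m, so a monitor's own cell takes its
  observed ratio almost exactly; sites beyond 300 km get weight 0 and the
  correction tapers to 1 (ratio space) as distance → radius.
* Observed species ratios use the same sampler's total (not a network
  total), and are clipped to [0, 1] before correction.
* Regression through the origin in the calibration; `r_squared` there is
  reported about the mean of the response, so it can be negative for a
  badly mis-specified slope — treated as degenerate input.
* The 1-in-3-day temporal gap-fill interpolates log-corrections linearly
  and holds endpoints constant; a site with a single sampling day
  contributes a constant correction.

## Problem sizes

The default study conditions (30 × 30 × 120, 38 sites) run the full
pipeline — generation, calibration, fusion including 10-fold CV, and
aggregation — in a few seconds. The test suite builds three studies of
this or smaller size once and reuses them across tests.

## Known limitations

* The fusion's spatial weighting is a declared stand-in with the
  qualitative contract (exact near monitors, model-shaped far away); the
  exact scheme of operational data-fusion products differs in detail and
  is isolated behind `fusion_config()`.
* Emission factors are a single-fuel placeholder; no combustion-phase
  split, plume rise, or diurnal profile.
* Planar geometry throughout; geographic inputs need prior projection.
* The calibration assumes permits are unbiased; with partial permit
  coverage the retained zero-permit keys shrink the fitted slope by the
  coverage factor, which is the documented trade-off of not discarding
  unmatched detections.
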