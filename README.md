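# pfsmoke

Estimating prescribed-fire (PF) contributions to ambient PM2.5 and its
chemical components — elemental carbon (EC), organic carbon (OC), nitrate,
sulfate — from paired chemical-transport-model simulations, fire records,
and monitor networks.

Prescribed burning is the dominant fuel-management tool in regions like the
southeastern US, and a major PM2.5 source there. Quantifying its
contribution requires stitching together satellite fire detections (biased,
incomplete), burn permit records (accurate, partial coverage), model
simulations (complete, biased), and monitor observations (accurate,
sparse). `pfsmoke` implements that chain as composable, tested stages:

1. **Burned-area calibration** — satellite and permit areas matched on
   gridded daily keys; least-squares scaling factor of permit on satellite
   area through the origin.
2. **Emissions** — the generic fire-emissions equation:
   emission = area × fuel load × consumption fraction × emission factor.
3. **Zero-out attribution** — the PF field is the difference of a baseline
   run and a run without PF emissions:
   ΔC_PF(x,t) = C_all(x,t) − C_no-PF(x,t).
4. **Data fusion** — per-day polynomial bias correction plus tapered
   inverse-distance interpolation of residual log-ratios for total PM2.5;
   PF impact rescaled as ΔC_PF^DF = ΔC_PF × C^DF / C^sim; components fused
   through species-to-total *ratios* so fused component masses always sum
   to the fused total (mass balance by construction).
5. **Evaluation** — MB/RMSE/NMB/NME/MNB/MNE/R², site-held-out 10-fold
   cross-validation, model-performance benchmark flags, and a plausibility
   diagnostic counting cell-days where estimated PF exceeds the observed
   total.
6. **Aggregation** — exact polygon coverage weights (rectangle clipping +
   shoelace), area-weighted zonal daily means, seasonal summaries
   (mean ± SD, median), PF shares, and exceedance statistics.

A first-class **synthetic-study generator** produces every input with known
ground truth (burn events with JFMA-heavy seasonality, degraded
satellite/permit records, a mass-conserving toy dispersion model, biased +
plume-displaced "model" fields, and noisy monitor observations on realistic
schedules), so the whole pipeline is testable end to end without any
external data. See the methods vignette
(`vignettes/prescribed-fire-attribution.Rmd`) for the model, assumptions,
and design rationale.

## Worked example

```r
library(pfsmoke)

cfg <- pipeline_config(seed = 1)   # 30x30 grid at 12 km, 120 days over 2021
r   <- run_pipeline(cfg)

r$calibration
#> pf_calibration: slope 0.5962 (intercept 0.000), n = 1038, R2 = 0.834

r$performance$sim          # raw model vs observations (collocated)
#> pf_perf_stats: n=3618 MB=-2.207 RMSE=2.960 NMB=-20.9% NME=22.9% ... R2=0.501

r$cv$pooled$fused          # fused vs observations at held-out sites
#> pf_perf_stats: n=3618 MB=-0.008 RMSE=1.773 NMB=-0.1% NME=11.3% ... R2=0.594

r$diagnostic_counts        # cell-days with PF estimate > observed total
#>   sim fused
#>     5     0

subset(r$period_summary, year == "all")
#>   year season   n  mean    sd median
#> 5  all   JFMA  40 0.741 0.237  0.703
#> 6  all  MJJAS  51 0.230 0.176  0.181
#> 7  all    OND  31 0.472 0.224  0.459
#> 8  all    all 122 0.459 0.303  0.393
```

Reading this: the satellite record over-reports area (the fitted 0.60
rescales it toward permits; with 90% permit coverage the slope sits
slightly below the generating factor 0.66 because unmatched detections are
kept as zero-permit pairs). The raw model underestimates PM2.5 by ~21%
network-wide; fusion removes that bias and improves held-out RMSE
(2.96 → 1.77 µg/m³) and R² (0.50 → 0.59), and eliminates all five
physically implausible PF estimates. Regional PF-PM2.5 averages
0.46 µg/m³ overall and 0.74 µg/m³ in the January–April extensive burning
season — the seasonal contrast the burn calendar should produce.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/run_pipeline.R --seed 1 --out artifacts/
```

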