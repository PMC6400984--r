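# paddysma

Rice yield estimation from six-band UAV imagery at heading stage, using
fully constrained spectral unmixing to correct vegetation indices for
panicle emergence.

## The problem

Once rice panicles start emerging, every pixel of a canopy image mixes
leaf, panicle and soil signal. Vegetation indices (VIs) computed from
such mixed spectra lose much of their correlation with final grain
yield, because the panicle fraction perturbs the spectrum without
carrying the canopy-vigour information the index is meant to read — and
emergence is uneven across plots. `paddysma` implements the
unmixing-based correction: estimate each plot's sub-pixel composition by
fully constrained least-squares (FCLS) spectral mixture analysis and
weight the VI by the leaf/panicle balance.

The core model, per pixel with reflectance `ρ_λ` at the six bands
(490, 550, 670, 720, 800, 900 nm):

```
ρ_λ = Σ_i Abd_i · ρ_λ(i) + e ,   0 ≤ Abd_i ≤ 1 ,  Σ_i Abd_i = 1
```

over six endmembers — top/bottom-layer leaf (TL, BL), top/bottom-layer
panicle (TP, BP), dry/wet soil (DS, WS). Plot-level leaf and panicle
abundance are `Abd_L = TL + BL` and `Abd_P = TP + BP` (means over the
plot rectangle), and yield is regressed on four predictor families per
index: `VI`, `VI·Abd_L`, `VI·Abd_P` and `VI·Abd_L-P` with
`Abd_L-P = Abd_L − Abd_P`. Final models are assessed by leave-one-out
cross-validation (`Coef = mean Coef_i`, `R² = mean R_i²`,
`RMSE = sqrt(mean E_i²)`).

Upstream of the statistics the package provides empirical-line
radiometric calibration (per-band `ρ = DN·Gain + Offset` fitted by least
squares over four ground panels), the ten standard indices of the
analysis (SR, CI_rededge, CI_green, NDVI, GNDVI, NDRE, VARI, MTCI, EVI,
EVI2), plot-rectangle zonal aggregation, and a seeded synthetic-scene
generator that emulates a 24-plot nitrogen trial (8 rates × 3
replicates, 18000 pixels per plot) so every stage is verifiable without
field data. The FCLS solver (Lawson–Hanson active set with a weighted
sum-to-one row) is implemented in C++ and unmixes the full ~500k-pixel
scene in seconds.

## Worked example

```r
library(paddysma)

run <- run_pipeline(scene_config(plot_rows = 40, plot_cols = 32, seed = 7),
                    vis = vi_names())
run
#> <pipeline_run> seed 7, 24/24 plots fitted
#>   best model: MTCI x Abd_L (adj R2 0.761, RMSE 0.164)
#>   LOOCV NDRE_LP: yield = 12.027 x + 0.989, R2 0.665, RMSE 0.223
#>   LOOCV GNDVI_LP: yield = 6.066 x + 0.937, R2 0.689, RMSE 0.214

run$correlations[run$correlations$predictor %in%
                   c("NDRE", "NDRE_L", "NDRE_P", "NDRE_LP"), ]
#>  predictor          r      p_value stars
#>       NDRE  0.3090285 1.417380e-01
#>     NDRE_L  0.8705469 3.200936e-08    **
#>     NDRE_P -0.7005445 1.378097e-04    **
#>    NDRE_LP  0.8182960 1.031954e-06    **
```

The pipeline simulated a heading-stage scene (seed 7), calibrated the DN
raster from its four panels, unmixed every pixel against the
six-endmember library, and fitted the yield models. The correlation rows
show the heading-stage pattern the method exists for: plain NDRE is a
weak yield predictor here (r = 0.31, not significant) because panicle
emergence confounds it; multiplying by leaf abundance (r = 0.87) or by
the leaf–panicle difference (r = 0.82) restores a strong positive
relationship, while the panicle-weighted index correlates negatively
(r = −0.70). The leave-one-out models report the fold-averaged
coefficients and the RMSE over held-out plots, in yield units.

The same analysis at full scene size, stage by stage with all
intermediates written under `results/run/`:

```sh
Rscript analysis/01_simulate.R      # DN raster + ground truth
Rscript analysis/02_calibrate.R     # empirical line, reflectance, QC
Rscript analysis/03_unmix.R         # FCLS abundance planes + plot table
Rscript analysis/04_indices.R       # ten VIs, merged plot table
Rscript analysis/05_yield_model.R   # correlations, ranking, LOOCV
```

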