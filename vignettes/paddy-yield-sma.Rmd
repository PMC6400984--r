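---
title: "Unmixing-weighted vegetation indices for rice yield estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unmixing-weighted vegetation indices for rice yield estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Vegetation indices (VIs) computed from canopy reflectance are reliable
yield predictors for rice while the canopy is pure leaf. At heading stage
the panicles emerge — unevenly across plots — and every image pixel
becomes a mixture of leaf, panicle and background soil. The panicle
fraction perturbs the canopy spectrum without carrying the chlorophyll
signal the VI is meant to read, so VI–yield correlations degrade exactly
when a late-season yield forecast would be most useful.

`paddysma` implements the remedy this package is built around: estimate
the sub-pixel composition of each plot by linear spectral mixture
analysis, and weight the VI by the leaf/panicle balance. The workflow is

1. **Empirical-line calibration** — per band, fit
   `reflectance = DN * gain + offset` by ordinary least squares over
   ground panels of known reflectance (nominals 0.06, 0.24, 0.48, 1.0)
   and apply it per pixel.
2. **Fully constrained least-squares unmixing (FCLS)** — per pixel, find
   abundances `a` minimising `||rho - E' a||` subject to `a >= 0` and
   `sum(a) = 1`, where the rows of `E` are six endmember spectra:
   top/bottom-layer leaf (TL, BL), top/bottom-layer panicle (TP, BP),
   dry/wet soil (DS, WS). Plot-level leaf and panicle abundance are
   `Abd_L = mean(TL) + mean(BL)` and `Abd_P = mean(TP) + mean(BP)`.
3. **Vegetation indices** — ten standard indices (SR, CI_rededge,
   CI_green, NDVI, GNDVI, NDRE, VARI, MTCI, EVI, EVI2) evaluated per
   pixel and then averaged over each plot rectangle.
4. **Yield regression** — simple linear fits of yield against four
   predictor families per index: `VI`, `VI*Abd_L`, `VI*Abd_P` and
   `VI*(Abd_L - Abd_P)`; the selected final models are assessed by
   leave-one-out cross-validation with the fold-mean convention:
   coefficients and R² are averaged over folds, RMSE is
   `sqrt(mean(E_i^2))` over the held-out errors.

No field campaign accompanies the package, so a seeded synthetic-scene
generator supplies ground truth for every stage; all tests and the
acceptance checks run against it.

## The synthetic trial

`scene_config()` emulates a nitrogen-response trial: 8 nitrogen rates
(0–19.5 kg/ha) × 3 randomly placed replicates = 24 plots, each a
150 × 120-pixel rectangle (18000 pixels) separated by soil ridges, plus
four uniform calibration panels. Two latent variables drive each plot:

* **Canopy greenness** `C = 0.725 + 0.25*u + N(0, 0.03)`, with `u` the
  nitrogen level scaled to [0, 1]. Greenness is what a chlorophyll-
  sensitive VI is supposed to measure.
* **Panicle emergence**: plot-mean panicle abundance
  `P = 0.005 + 0.02*u + Gamma(mean 0.045, sd 0.07)`, clamped to
  [0.001, 0.30]. The gamma term makes emergence *uneven*: two plots at
  the same nitrogen rate can differ several-fold in visible panicle.
  Across plots this reproduces the skewed distribution of real
  heading-stage panicle fractions (most plots near 0.03, a tail to
  ~0.25, population mean ≈ 0.06), while leaf abundance
  `L = 1 - soil - P` concentrates near 0.93.

Yield follows `yield = 1.55 + 2.8 * C * (L - P) + N(0, 0.18)`, i.e. the
grain output of the green, non-panicle canopy. The defaults give a yield
population with mean ≈ 3.61 and CV ≈ 12% on the study's (unitless) scale.
Because yield rises with `C` but falls with `P`, while the plain VI reads
mostly `C`, the abundance-difference product `VI*(Abd_L - Abd_P)` is the
correctly specified predictor by construction — the package's central
qualitative claim is therefore testable: correlations must come out
positive for `VI*Abd_L`, negative for `VI*Abd_P`, and
`NDRE*(Abd_L-Abd_P)` must out-fit plain NDRE on the large majority of
seeds.

Within a plot, per-pixel abundances are Dirichlet-style draws (gamma
fields with concentration 80, box-smoothed with a 5 × 5 window for
spatial coherence, then normalised) around the plot means, so every pixel
sums to one exactly. Pixel reflectance is the exact abundance-weighted
mixture of the six library spectra; the DN image inverts the true
per-band affine calibration (gains ≈ 0.001 reflectance/DN, offsets
±0.02) and adds Gaussian noise with sd 2 DN.

### How greenness reaches the spectra

A design question with no prescribed answer was how `C` should show up in
the imagery. The obvious mechanism — per-plot multiplicative modulation of
the leaf endmember spectra (chlorophyll-dependent red absorption) — fails
in an instructive way: any modulation large enough to move NDRE by a few
hundredths lies outside the simplex spanned by the library, and the
constrained solver reallocates it into the *panicle* fractions. The
estimated `Abd_P` then correlates with greenness rather than with true
panicle cover, and plot-level abundance errors exceed 0.02. The package
instead couples greenness to canopy *structure*: the top-layer (sunlit)
leaf share is `tau = 0.65 + 1.4 * (C - mean C)`, bounded to [0.20, 0.95].
Because the shaded bottom-layer leaf spectrum is genuinely different
(shade suppresses the NIR plateau more than the visible bands — the shade
factor falls from ≈ 0.6 at 490 nm to ≈ 0.32 at 900 nm), a higher sunlit
share raises canopy NDRE; and because the mixture stays inside the
library simplex, unmixing remains exact in the noiseless limit and the
panicle planes stay clean under noise. The same wavelength-dependent
shading is what keeps the 6 × 6 library numerically well-conditioned:
scalar-copy bottom layers would make TL/BL and TP/BP collinear.

### Endmember spectra

`generate_endmember_library()` builds smooth 1-nm spectra (spline through
fixed anchors, plus a seeded 2% low-frequency wiggle) encoding the
qualitative contrasts of field-measured paddy endmembers: leaf ≈ 7% and
panicle ≈ 5% reflectance in the blue; leaf well above panicle in the NIR
but slightly below it in the red; bottom layers darker than top at every
band with bottom leaf still above bottom panicle in the NIR; wet soil
below dry soil at every wavelength. Spectra are band-averaged onto the
six 10-nm camera bands (490, 550, 670, 720, 800, 900 nm) by the
trapezoid mean over the closed interval center ± 5 nm — symmetric about
the center, flat within the band, no spectral-response weighting.

## Numerical choices

* **FCLS solver.** The sum-to-one constraint is an appended row with
  weight `delta = 1e3 * max|E|` inside a Lawson–Hanson non-negative
  least-squares active-set iteration; the solution is renormalised so the
  simplex constraint holds exactly (the renormalisation is O((resid/δ)²),
  far below the reported precision). Degenerate all-zero solutions fall
  back to the uniform simplex point. Correctness is gated on an
  *independent* brute-force simplex-lattice enumerator: the solver's
  squared residual must not exceed the lattice minimum (step 0.01 for
  3-endmember problems; step 0.02 for the 6-endmember library, whose
  0.01-lattice has ~10⁸ points) plus 1e-5.
* **Calibration** is fitted per band independently, on the arithmetic
  mean DN of each panel rectangle. Out-of-range reflectance (< 0 or > 1)
  is *not* clipped — clipping would bias both the indices and the
  unmixing — but the out-of-range fraction is reported by
  `calibration_qc()`.
* **Index masking.** A pixel is masked invalid when a VI denominator
  magnitude falls below 1e-9 (this happens for MTCI on soil pixels where
  the 720 and 670 nm reflectances coincide); plot means are taken over
  valid pixels only and the invalid fraction is reported. VARI is
  implemented in its two-band green–red form
  `(rho550 - rho670)/(rho550 + rho670)`; some published VARI variants
  include a blue term, which is deliberately not used here.
* **Plot statistics** are always per-pixel-first: the index (or
  abundance) is computed per pixel and then averaged over the plot
  rectangle, not computed from the plot-mean spectrum. The alternative
  ordering is not exposed.
* **LOOCV convention.** The fold R² entering the reported average is the
  *training* coefficient of determination of each fold — with a single
  held-out sample per fold no validation R² exists. This makes the
  cross-validated R² optimistic relative to a held-out R²; the RMSE, by
  contrast, is computed purely from held-out errors.
* **Noiseless limit.** With `noise_sd_dn = 0`, `yield_noise_sd = 0` and
  constant greenness (`greenness = c(0.85, 0, 0)`) the pipeline is exact:
  fitted gains/offsets reproduce the generating values to machine
  precision, per-pixel abundances match the truth below 1e-6, and —
  because yield is then exactly affine in `Abd_L - Abd_P` — the
  best-ranked model fits with RMSE below 1e-6. (The model ranking
  includes the three abundance-only predictors alongside the VI grid for
  this reason; yield-versus-abundance fits are part of the analysis in
  their own right.)
* **Panels in the truth map.** Calibration-panel pixels carry their
  nominal reflectance in every band; they are flagged as pure dry soil in
  the truth abundance map by convention and excluded from
  abundance-recovery comparisons.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `noise_sd_dn` | 2 | DN | sensor noise; ≈ 0.002 reflectance at the default gains |
| `gain`, `offset` | ≈ 0.001, ±0.02 | refl/DN, refl | true affine calibration per band |
| `concentration` | 80 | — | within-plot Dirichlet scatter (larger = more uniform) |
| `smooth_half` | 2 | px | half-width of the spatial box filter on abundance fields |
| `greenness` | (0.725, 0.25, 0.03) | — | intercept, nitrogen slope, sd of the latent C |
| `greenness_coupling` | 1.4 | — | slope of top-layer leaf share on C |
| `panicle` | (0.005, 0.02, 0.045, 0.07) | — | base, nitrogen slope, emergence-noise mean and sd |
| `soil_in_plot` | 0.01 | — | mean soil abundance inside plot rectangles |
| `yield_coefficients` | (1.55, 2.8) | yield units | β0, β1 of the yield model |
| `yield_noise_sd` | 0.18 | yield units | unexplained yield variation |

The generator parameters were fixed once against the design targets
(abundance means/ranges, yield scale and CV, and the qualitative
correlation pattern) and are not tuned per analysis.

## What the tests do and do not show

The test suite verifies, on synthetic scenes: exact recovery in the
noiseless limit; solver optimality against brute-force enumeration;
plot-level leaf/panicle abundance recovery within 0.02 mean absolute
error under sensor noise at the full 24 × 18000-pixel scale; and the
qualitative heading-stage pattern (positive `VI*Abd_L`, negative
`VI*Abd_P` correlations, `NDRE*(Abd_L-Abd_P)` out-fitting plain NDRE) in
at least 90% of seeded trials. Unit and property tests run the same 8 × 3
design at reduced plot sizes (12 × 10 to 40 × 32 pixels) to keep the
suite fast; the full-size scene is exercised in the end-to-end checks.

What passing these tests does **not** show: the generator contains no
bidirectional reflectance effects, no atmospheric or illumination drift,
no georeferencing or band misregistration error, no within-plot endmember
variability (every plot mixes the same six spectra), and its yield model
is exactly the linear structure the analysis assumes. Real heading-stage
imagery violates all of these to some degree; on real data the pipeline's
*relative* ordering of predictor families is the transferable claim, not
the absolute R² values, which are optimistic here.

## Limitations

* The FCLS formulation assumes linear mixing; multiple scattering between
  canopy layers is nonlinear in reality.
* Only simple one-predictor linear yield models are provided — no
  multi-index, nonlinear or mixed-effects variants.
* The excluded-plot mechanism (`exclude_plots`) is manual by design;
  no automatic outlier rejection is performed.
* Abundance estimates inherit a small positive bias on components whose
  true abundance is near zero (the non-negativity constraint clips noise
  asymmetrically); at the default noise level this stays within the
  0.02 plot-level error budget but it grows with sensor noise.
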