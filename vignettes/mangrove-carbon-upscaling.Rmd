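---
title: "From UAV reflectance to mangrove carbon assimilation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From UAV reflectance to mangrove carbon assimilation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(mangroveflux)
```

`mangroveflux` maps annual carbon assimilation of mangrove stands by
chaining four models: a radiometric sensor model, an empirical LAI
regression, a light-use upscaling identity, and a reflectance-threshold
canopy mask. This vignette explains each one, the assumptions it rests
on, the tunable parameters, and the design decisions that were open
when the package was written.

## 1. Radiometric model

Raw frames record normalized digital numbers $\rho \in [0,1]$ (counts
divided by the sensor maximum). Spectral radiance is obtained per pixel
from

$$L = V(x,y)\,\frac{a_1}{g}\,
      \frac{\rho - \rho_{BL}}{t_e + a_2 y - a_3 t_e y},$$

with $V(x,y) = 1/(1 + \sum_{i=1}^{6} k_i r^i)$ a radial vignetting
polynomial ($r$ = pixel distance to the vignetting centre), $g$ the
sensor gain, $t_e$ the exposure time (s), $\rho_{BL}$ the normalized
black-current level, and $a_{1..3}$ per-band calibration coefficients.
Reflectance follows by normalizing against a panel of known reflectance
(default 0.20): $R = L / L_\text{panel} \times R_\text{panel}$.

Three conventions had to be fixed because the sensor vendor's note
leaves them open at the level of the equation itself:

* **Row index.** $y$ is the 0-based row index from the top of the
  frame (a row-wise readout compensation). Any consistent convention
  would work; this one is documented and tested.
* **Vignetting form.** The radial six-coefficient inverse polynomial
  above matches the published model shape of the sensor family;
  coefficients always come from per-band metadata (JSON sidecar) and
  are never assumed.
* **Negative values.** Radiance and reflectance below zero are
  physically impossible but numerically expected for dark pixels near
  the black level. They are *preserved and counted* (attributes
  `n_negative`, `n_out_of_range`; surfaced in the pipeline manifests)
  rather than clipped, because the count is a useful quality signal of
  the correction. An optional `clip` argument exists for display.

## 2. Feature layers

Seven band-combination indices are computed from the five reflectance
bands, plus the canopy height model:

```{r}
index_names()
predictor_names()
```

CHM $=$ DSM $-$ DTM, with negative differences clamped to zero: a
surface model below the terrain model is reconstruction noise, not
canopy. Zero denominators in an index give NoData rather than
infinities, and NoData in any input band propagates.

The `RE.Green` index, $(\rho_{717}-\rho_{560})/(\rho_{717}+\rho_{560})$,
is implemented exactly as defined even though it is the one index
without an established literature pedigree; dropping or "fixing" it
would silently change the 13-predictor model.

## 3. Plot aggregation

Ground truth is one LAI value per 10 × 10 m plot: five below-canopy
readings averaged arithmetically. Image predictors are averaged over
the plot footprint with these rules, which the field protocol does not
itself pin down:

* a pixel belongs to the footprint when its **centre** falls inside the
  axis-aligned square (half-open edges, so abutting plots never share
  pixels);
* NoData pixels are excluded from the mean rather than invalidating
  the plot, but a footprint must retain at least 25 % valid pixels for
  every predictor (`min_valid`), else the plot errors out by name —
  robustness to small orthomosaic gaps without letting a nearly empty
  footprint masquerade as data;
* all grids must share the georeference exactly; this package never
  resamples.

## 4. The LAI regression

LAI is regressed on the 13 predictors with ordinary least squares
(`stats::lm`), pooling all study areas into a single model. No
standardization is applied before fitting — coefficients stay in LAI
units per predictor unit, and the importance decomposition below is
scale-free anyway. Rank-deficient designs are rejected with the names
of the collinear columns rather than silently dropping terms.

Three reporting conventions matter when comparing numbers:

* **RMSE** uses the $1/n$ denominator, not $1/(n-p-1)$: a single RMSE
  is reported without degrees-of-freedom language, and this choice
  makes the fit RMSE directly comparable to the cross-validated RMSE.
* **LOOCV.** Each observation is predicted from a model fitted to the
  other $n-1$ rows. The implementation uses the exact OLS identity
  $e_{(-i)} = e_i/(1-h_{ii})$ (hat-matrix leverages) instead of $n$
  refits; the test suite proves the identity against explicit refits.
  $R^2_{cv}$ is computed against the total sum of squares of the full
  response so it shares a scale with the training $R^2$.
* **LMG importance.** A predictor's contribution is its average
  increase in $R^2$ over all $p!$ orders of entry. This is computed
  exactly by enumerating all $2^p$ subsets with the ordering weights
  $|S|!\,(p-|S|-1)!/p!$, on centred cross-products so each subset costs
  one small linear solve. Shares are reported as percentages of the
  full-model $R^2$ (summing to 100); the absolute $R^2$ shares are also
  returned. Enumeration is bounded at $p \le 20$; for the package's 13
  predictors ($2^{13}$ subsets) it takes a few seconds.

Wall-to-wall prediction applies the fitted linear combination per
pixel, clamps negative predictions to zero (LAI is non-negative), and
propagates NoData from any predictor layer.

## 5. Carbon upscaling

Net canopy photosynthesis is the light-attenuation identity
$P_N = A \cdot d \cdot \mathrm{LAI}$: the mean leaf-level net
photosynthesis $A$ (μmol CO₂ m⁻² s⁻¹) is assumed to apply over every
layer of leaf area for $d$ daylight hours. Annual per-pixel carbon is

$$\text{kg C pixel}^{-1}\,\text{yr}^{-1}
  = P_N\,[\text{mol m}^{-2}\,\text{day}^{-1}]
    \times 365 \times 12.011 \times A_{px} \times 10^{-3},$$

with $A_{px}$ the pixel area in m². Parameters and defaults:

| parameter | default | unit | rationale |
|---|---|---|---|
| `daylight_hours` | 11.6 | h | annual mean day length at the Red Sea study latitude |
| `molar_mass_c` | 12.011 | g mol⁻¹ | one mol CO₂ fixes one mol C; validated by reproducing the 10.35 μmol ↔ 0.45 g C m⁻² h⁻¹ equivalence |
| `days_per_year` | 365 | d | calendar year; "ton" is the metric tonne |
| `pixel_area` | georef `pixel_size²` | m² | an explicit override (e.g. 51.41 cm²) exists because survey-native pixel areas are sometimes reported separately from the nominal pixel size |
| mask thresholds | NDVI > 0.1, NIR > 0.1, Red < 0.2 | — | empirically derived canopy thresholds; strict inequalities exactly as defined |

$A$ is the *pooled* mean across areas by default — the field campaigns
are assumed physiologically interchangeable — with per-area summaries
(`flux_summary(by = "area")`) available when that assumption is not
wanted. The per-area carbon rate in ton C km⁻² yr⁻¹ equals
g C m⁻² yr⁻¹, and the package reports full-precision values, rounding
only for display. The mean across areas (`average_rate()`) is
unweighted, treating each stand as one observation regardless of size.

Note the structural assumptions inherited from the identity: no light
saturation with canopy depth, no respiration term (this is *net
daytime* assimilation, not NEE), and a single $A$ for all pixels.
Heterogeneity enters only through LAI.

## 6. What the synthetic generator does and does not emulate

`generate_scene()` builds patchy canopies whose spectra follow a
Beer–Lambert-style saturation: each band moves from its bare-soil value
toward its dense-canopy value as $1 - e^{-k\,\mathrm{LAI}}$, the same
light-attenuation rationale that underlies optical LAI instruments.
The red band declines with LAI and NIR is solved so that NDVI follows
the saturation curve *exactly*, which makes the construction invertible
(`invert_ndvi_lai()`) and lets tests verify recovery without noise.
Canopy height is `chm_gain` (0.7 m per LAI unit) times LAI plus noise;
water and soil backgrounds get flat spectra that fail the canopy mask.
Defaults mirror the study conditions: canopy LAI spanning about
0.15–4.5, 119 plots across three areas (39/40/40), and leaf-flux
records whose deterministic part declines from a morning maximum
(0.6 μmol CO₂ m⁻² s⁻¹ per hour), offset per area (summer > autumn >
winter at dawn), pooled mean 10.35 μmol CO₂ m⁻² s⁻¹, record noise SD
4.5 (giving pooled CVs around 50 %, within the 38–77 % range observed
per area in the field), and a 12:00–16:00 sampling gap in the two warm
seasons. Scenes default to 400 × 400 pixels at 0.5 m — large enough to
hold 119 non-overlapping 10 × 10 m plots while keeping a full pipeline
run under a few seconds.

What it deliberately does **not** emulate: radiative-transfer realism
(no PROSAIL-class bidirectional effects), tides or water-line movement,
spatially correlated sensor noise, georeferencing error, and the
fine-scale crown architecture of real stands. Green tests on synthetic
scenes therefore demonstrate that the *pipeline machinery* is correct
and self-consistent — they cannot certify the empirical skill of the
regression on any real mangrove site, which depends on field data
quality and on how well the linear model fits that site's
canopy-spectra relationship. The near-perfect synthetic R² (~0.95)
reflects the generator's benign noise structure, not expected field
performance.

## 7. Numerical choices and degenerate inputs

* Zero index denominators → NoData; NoData → excluded from plot means,
  `FALSE` in masks, propagated in maps.
* Negative CHM → 0; negative predicted LAI → 0; negative radiance →
  preserved and counted (see §1).
* Plot readings in the generator are truncated at 0, as an optical
  instrument would report.
* All randomness flows from one integer seed per scene configuration;
  derived streams (plots, flux) use fixed small offsets from it, so a
  scene and its field campaign are jointly reproducible.
* Rasters are exchanged as plain-text ESRI ASCII grids with a NoData
  sentinel; models as JSON; tables as CSV. Re-running any pipeline
  stage with unchanged inputs and seed is byte-identical apart from
  manifest timestamps.

## 8. Problem sizes

The test suite and the acceptance script run synthetic campaigns at the
study's field scale — 119 plots, 13 predictors — on 400 × 400-pixel
scenes (240 × 240 for unit-level fixtures), with 200 seeded replicates
for the coefficient-recovery checks. These sizes were chosen so a full
verification pass completes in about a minute on a laptop while keeping
every statistical check at the field-campaign dimensions that matter
(n = 119 rows against p = 13 predictors).

## 9. Known limitations

* The LAI model is a pooled linear regression; transfer to sites with
  different stand structure, species composition, or viewing/illumination
  geometry is not addressed (and machine-learning estimators are out of
  scope by design).
* Carbon totals scale linearly in $A$ and $d$: biases in the leaf-level
  campaign (e.g. only healthy, sun-facing leaves sampled) propagate
  one-to-one to the maps, likely toward the upper range of stand-level
  assimilation.
* The canopy mask is a hard threshold triple; mixed pixels at canopy
  edges are either fully in or fully out at the native resolution.
* The diurnal decline in the flux generator is linear; a plain loess
  smoother is drawn in `plot_diurnal_flux()` for orientation only and
  plays no role in any computation.
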