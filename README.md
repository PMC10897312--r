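# mangroveflux

Quantify carbon assimilation in mangrove stands from UAV multispectral
surveys.

Mangroves are among the most effective carbon-fixing ecosystems, and in
arid coastal settings they are often the only woody vegetation available
for carbon sequestration. Measuring how much carbon a stand assimilates,
however, usually requires either expensive eddy-covariance towers or
laborious point-scale field campaigns. `mangroveflux` implements a
light-attenuation upscaling route instead: leaf area index (LAI), a
direct measure of photosynthesising leaf area per unit ground area, is
mapped wall-to-wall from drone imagery and combined with leaf-level gas
exchange measurements to produce annual carbon-assimilation maps.

The package is aimed at remote-sensing ecologists working with
five-band multispectral cameras (475, 560, 668, 717, 842 nm), ground
LAI readings from plant-canopy analysers, and chamber-based net
photosynthesis measurements.

## The method

1. **Radiometric correction.** Raw digital numbers are converted to
   spectral radiance with the vicarious (sensor-information-based)
   correction

   *L* = *V*(x, y) · (a₁/g) · (ρ − ρ_BL) / (tₑ + a₂·y − a₃·tₑ·y)

   where *V* is a radial vignetting polynomial, *g* the sensor gain,
   tₑ the exposure time, ρ the normalized pixel value and ρ_BL the
   black-current level; radiance becomes surface reflectance through a
   known reflectance panel (~20 %).

2. **Feature layers.** Seven vegetation indices (blueNDVI, greenNDVI,
   NDRE, NDVI, NIR.RE.Red, RE.Green, RENDVI) plus the canopy height
   model CHM = DSM − DTM give, with the five bands, 13 predictor
   layers.

3. **LAI regression.** Ground LAI (five readings averaged per
   10 × 10 m plot) is regressed on the plot-mean predictors with
   ordinary least squares; skill is reported both on the fit and under
   leave-one-out cross-validation, and each predictor's contribution is
   decomposed with the LMG relative-importance rule (average R² gain
   over all orderings, computed by exact subset enumeration).

4. **Carbon upscaling.** Net canopy photosynthesis per pixel is
   *P*_N = *A* · *d* · LAI, with *A* the mean measured leaf-level net
   photosynthesis (μmol CO₂ m⁻² s⁻¹) and *d* the mean daylight duration
   (default 11.6 h). *P*_N is integrated to kg C pixel⁻¹ yr⁻¹
   (12.011 g C mol⁻¹, 365 days), summed over the mangrove mask
   (NDVI > 0.1, NIR > 0.1, Red < 0.2) and reported as ton C yr⁻¹ totals
   and ton C km⁻² yr⁻¹ rates.

Because real campaigns of this kind are rarely public, the package
ships a seeded synthetic-scene generator (`generate_scene()`,
`sample_plots()`, `generate_leaf_flux()`) that reproduces the
statistical structure the analysis assumes, so the whole pipeline can
be exercised and tested end to end.

## Worked example

```r
library(mangroveflux)

cfg    <- scene_config(seed = 42)          # synthetic study area
scene  <- generate_scene(cfg)
plots  <- sample_plots(scene)              # 119 field plots
chm    <- compute_chm(scene$dsm, scene$dtm)

tab    <- predictor_table(scene$stack, chm, plots)
model  <- fit_lai_model(tab)
glance(model)
#> # A tibble: 1 × 6
#>       n     p r2_fit rmse_fit r2_loocv rmse_loocv
#>   <int> <int>  <dbl>    <dbl>    <dbl>      <dbl>
#> 1   119    13  0.949   0.0981    0.933      0.113

flux <- generate_leaf_flux(cfg)
flux_summary(flux)
#> # A tibble: 1 × 5
#>   group      n mean_a mean_a_gC_h cv_pct
#>   <chr>  <int>  <dbl>       <dbl>  <dbl>
#> 1 pooled   290   10.0       0.434   55.0

lai_map <- predict_lai_map(model, scene$stack, chm)
carbon  <- annual_pixel_carbon(flux_summary(flux)$mean_a, lai_map,
                               carbon_constants())
area_carbon_summary(carbon, mangrove_mask(scene$stack),
                    carbon_constants(), label = "demo")
#> # A tibble: 1 × 5
#>   area_label mangrove_pixels area_km2 total_tonC_yr rate_tonC_km2_yr
#>   <chr>                <int>    <dbl>         <dbl>            <dbl>
#> 1 demo                 73315   0.0183          81.1            4423.
```

The regression explains most of the LAI variance on this synthetic
scene (fit R² 0.95, cross-validated 0.93 — real campaigns are noisier),
the 290 leaf measurements average 10.0 μmol CO₂ m⁻² s⁻¹ (0.43 g C m⁻²
h⁻¹), and the 0.018 km² of canopy in the scene assimilates an estimated
81 ton C yr⁻¹, i.e. about 4420 ton C km⁻² yr⁻¹.

`autoplot(model)` draws the importance decomposition,
`autoplot(model, "fit")` the observed-vs-predicted scatter,
`autoplot(lai_map)` / `autoplot(carbon)` the maps, and
`plot_diurnal_flux(flux)` the diurnal course of the leaf measurements.

A staged command-line pipeline (`run_stage()`, stages `simulate`,
`indices`, `fit-lai`, `predict-lai`, `carbon`, `all`) with a YAML
configuration and per-stage JSON provenance manifests is available for
shell-driven runs; `inst/scripts/mangroveflux` is a thin wrapper around
it.

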