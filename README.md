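# cuttleoptics

Quantitative tools for an underwater visual-ecology field survey of dwarf
cuttlefish habitat: how seawater filters color with depth, what color
gamut is left at the depths where the animals live, whether the animals'
distribution over habitat and time of day is statistically real, and how
to put physical scale on texture photographs.

The package is aimed at researchers analyzing dive-based photographic
surveys: it turns a color-card depth series, flash photographs,
dive-computer logs, a sightings notebook and paired-laser images into
fitted models, gamut summaries, exact rate tests and scale calibrations.
A synthetic-data module generates all of these inputs under known ground
truth, so the entire pipeline is testable offline.

## What it computes

**Water-column color attenuation.** Ambient intensity in camera channel
*c* at depth *z* follows Beer–Lambert decay,

&nbsp;&nbsp;&nbsp;&nbsp;*I_c(z) = ρ_c E_c exp(−k_c z)*,

with reflectance *ρ_c*, surface illuminant *E_c* and per-channel diffuse
attenuation coefficient *k_c* (1/m; largest for red). `fit_attenuation()`
estimates *k* by log-linear least squares over the neutral panels of a
color card photographed at a series of depths; `simulate_at_depth()`
re-filters flash-lit images to their ambient appearance at depth.

**Hue–chroma gamut.** `rgb_to_hue_chroma()` converts linear RGB to
CIELAB (hue = atan2(b, a), chroma = √(a²+b²));
`depth_gamut_profile()` summarizes the convex hull of card colors in the
(a, b) plane per depth, overlaid with sighting depths.

**Effort-standardized encounter statistics.** `aggregate_effort()` turns
10-s dive logs into searcher-hours per (habitat × diel) stratum and
15-min / 1-m histograms; `expected_count()` transfers a discovery rate
across strata; `exact_poisson_rate_test()` is the conditional-binomial
exact comparison of two Poisson rates (for zero observed out of total
*n*, the one-sided p-value is (T₂/(T₁+T₂))ⁿ).

**Laser scale calibration.** `detect_laser_dots()` finds the two
parallel-laser dots (fixed 100 mm beam separation), `mm_per_pixel()`
derives the image scale and `scalebar_pixels()` converts a 20 mm scale
bar to pixels.

## Worked example

```r
library(cuttleoptics)

# fit the attenuation model from a synthetic card series (known truth
# k = 0.5, 0.07, 0.04 per meter; measurement noise sd 0.005)
opt <- water_optics(k = c(0.5, 0.07, 0.04), noise_sd = 0.005)
model <- fit_attenuation(render_card_series(opt, seed = 1))
model
#> Per-channel water attenuation model (exponential mode)
#>   k (1/m): R 0.49919  G 0.069914  B 0.039975
#>   log-RMSE: R 0.00428  G 0.0026  B 0.00188; excluded below eps: 49

round(predict_channel_scale(model, 10), 4)
#>      R      G      B
#> 0.0068 0.4970 0.6705
```

The fitted coefficients recover the generator's truth to a fraction of a
percent; at 10 m less than 1% of red light remains while two-thirds of
blue does — the quantitative form of "red disappears first". The 49
excluded points are deep red measurements below the 1/255 dark floor.

```r
# survey statistics at the campaign's printed effort totals:
# 25 animals, all at night (38.2 h searched) and all on reef (57.4 h)
expected_count(25, 38.2, 32.0)
#> [1] 20.94241
exact_poisson_rate_test(0, 32.0, 25, 38.2, "deficit")
#>  Exact Poisson rate test (conditional binomial)
#> data:  0 of 32 h vs 25 of 38.2 h
#> x1 = 0, n = 25.00000, p = 0.45584, p-value = 2.473e-07
```

Had daytime activity matched the nighttime discovery rate, 20.9 animals
were expected in the 32.0 daytime hours; observing zero has probability
2.5 × 10⁻⁷ under equal rates, establishing nocturnal activity.

```r
# millimeter-per-pixel from a synthetic paired-laser scene
img <- render_laser_scene(mm_per_px = 0.2, noise_sd = 0.01, seed = 1)
scalebar_pixels(mm_per_pixel(calibrate_scale(img)))
#> Scale bar: 20 mm = 100 px at 0.2 mm/px
```

An end-to-end run on synthetic data (all stages, CSV/JSON outputs and a
hashed manifest) is one call — `run_pipeline(pipeline_config(seed = 1))`
— or, from a shell, `exec/cuttleoptics run --seed 1 --out out/`.

## Documentation

The methods vignette
(`vignettes/underwater-color-and-survey-methods.Rmd`) describes the
model and its assumptions, the defaults that matter (dark floor, fit
panels, diel boundary, bin conventions), what the synthetic generators do
and do not emulate, and known limitations.
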