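# rosetrace

Monte-Carlo analysis of UV-B and PAR radiation interception on 3D rosette
canopies, with the downstream physiology and biochemistry toolchain of
controlled-environment UV-B supplementation studies.

## The problem

Supplemental UV-B in plant factories induces dose-dependent accumulation
of flavonoids and other phenolics — but a rosette crop like kale is not
irradiated uniformly. Leaf position, curvature and spiral phyllotaxis
make each leaf intercept a different UV dose, and leaf developmental age
independently shifts its biochemistry. Separating *intercepted dose* from
*leaf age* requires (i) a quantitative per-leaf radiation budget, which
only ray tracing over the 3D canopy can provide, and (ii) a regression
stage that decomposes the two effects on standardized scales.

`rosetrace` implements that chain end to end for users who want a
testable, scriptable version of this analysis:

* **Geometry** — parametric golden-angle (137.5°) rosette meshes with
  age-ordered insertion heights and a configurable per-leaf area profile;
  OBJ/PLY mesh I/O.
* **Transport** — a compiled analog Monte-Carlo tracer (BVH-accelerated)
  over leaf/furniture meshes with Lambertian LED emitters (truncated
  cosine, 60° half-angle), diffuse leaf optics per band, virtual-sensor
  power calibration, and an exact energy ledger
  `emitted = absorbed + escaped + terminated`.
* **Dosimetry** — band integration (PAR 400–700 nm, UV 280–400 nm), PPFD
  conversion, daily doses, and biologically effective UV weighting by the
  generalized plant action spectrum:
  `daily_dose(1.0 W m⁻², 12 h) = 43.2 kJ m⁻² d⁻¹`.
* **Fluorescence** — quenching analysis `Fv/Fm = (Fm − Fo)/Fm`,
  `NPQ = (Fm − Fm′)/Fm′`, `ΦPSII = (Fm′ − F′)/Fm′` on protocol-structured
  traces, plus a trace simulator for round-trip validation.
* **Assays** — DPPH radical scavenging `(A_blank − A_sample)/A_blank × 100`,
  calibration-curve quantification (mg CE or GAE g⁻¹ DW), and a synthetic
  per-leaf assay generator with the published standardized-effect
  structure.
* **Statistics** — Pearson correlations, multiple regression with
  standardized coefficients `b·sd(x)/sd(y)`, effect-size ratios, and
  per-leaf distribution summaries.

## Worked example

Build a ten-leaf rosette, calibrate the chamber's UV chips so a virtual
bed sensor reads 1.0 W m⁻², trace a million rays, and regress synthetic
per-leaf flavonoid contents on leaf order and intercepted dose:

```r
library(rosetrace)

ros     <- build_rosette(rosette_spec(seed = 42))
cal     <- calibrate_power(build_chamber(), target_w_m2 = 1.0,
                           band = "UV", n_rays = 1e6, seed = 1)
scn     <- add_plant(cal$scene, ros)
tally   <- trace(scn, n_rays = 1e6, bands = "UV", seed = 2)
leaf_interception(tally, "UV")[, c("leaf_order", "area_cm2", "irradiance_w_m2")]
#>  leaf_order area_cm2 irradiance_w_m2
#>           1    25.00          0.0957
#>           2    32.25          0.1625
#>           3    84.49          0.3481
#>           4   168.31          0.6316
#>           5   179.44          0.8016
#>           6   200.07          0.9896
#>           7   182.72          1.0468
#>           8   139.49          1.0785
#>           9    91.20          1.0342
#>          10    49.94          1.0082
```

Interception rises from the shaded bottom leaves to the exposed upper
canopy and saturates near the top — upper leaves sit close to the LED
plane, where chip beams overlap less. Converting to daily biologically
effective doses and fitting the regression stage:

```r
round(uvi_from_tally(tally), 2)   # kJ m^-2 d^-1 per leaf order
#>     1     2     3     4     5     6     7     8     9    10
#>  1.08  1.83  3.92  7.12  9.03 11.15 11.79 12.15 11.65 11.36

fit <- fit_regression(synth_assays(uvi = tally, seed = 3), "tfc")
fit
#> <regression_fit> tfc ~ lo + uvi (linear link), n = 56, R^2 = 0.871
#>        raw standardized
#> lo  0.1399       0.1451
#> uvi 0.4287       0.8888
round(effect_ratio(fit), 2)
#> [1] 6.13
```

The standardized coefficient of intercepted UV dose dominates that of
leaf age several-fold for flavonoid content. Any single 56-record draw
scatters around the generating ratio of 5 (the denominator is a small
coefficient, so per-draw ratios are noisy); averaging standardized
coefficients over replicate draws recovers the generating ratio to ~1% —
see the methods vignette (`vignettes/interception-methods.Rmd`) for the
estimator discussion.

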