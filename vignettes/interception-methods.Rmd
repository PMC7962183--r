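---
title: "From canopy photons to leaf biochemistry: the rosetrace methods"
author: "rosetrace authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From canopy photons to leaf biochemistry: the rosetrace methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rosetrace)
```

`rosetrace` models a question from controlled-environment plant
photobiology: when a rosette crop such as kale is grown under supplemental
UV-B LEDs, how much UV does each leaf actually intercept, and how much of
the leaf-to-leaf variation in UV-induced phenolics is attributable to that
intercepted dose rather than to leaf developmental age? The package covers
the full chain — synthetic 3D plant and chamber geometry, Monte-Carlo
radiative transport, biologically effective dosimetry, chlorophyll
fluorescence quenching analysis, assay arithmetic, and the
correlation/regression stage — so that every step is testable in code.

This vignette records the models, their assumptions, the tunable
parameters, and the design decisions that were genuinely open.

## Synthetic rosette geometry

Real interception studies 3D-scan their plants; scan meshes are rarely
released. `build_rosette()` therefore generates a parametric stand-in
constrained by what is known about rosette architecture:

* **Phyllotaxis.** Leaf $k$ sits at azimuth $(k-1)\,\delta \bmod 360°$
  with divergence angle $\delta = 137.5°$ (the golden angle) by default.
  For $n \le 10$ this guarantees no two leaves within $10°$ of each other,
  the packing property that spreads light capture around the axis.
* **Age ordering.** Leaf 1 is the oldest, bottom leaf; insertion height
  increases by a fixed internode (default 15 mm) and petiole elevation
  rises from 20° (spreading, senescent) to 65° (upright, expanding) along
  a convex ramp. Midrib droop (default 35° total bend) fades linearly with
  youth. These defaults were chosen by forward geometry checks so that
  area-weighted mean leaf height increases strictly with leaf order even
  under the generator's size/azimuth jitter — the qualitative feature the
  downstream "interception increases with height" analyses rely on.
* **Lamina.** Each leaf is an elliptic-outline lamina (half-width
  $\tfrac{W}{2}\sqrt{4s(1-s)}$ along the midrib) swept along the drooping
  midrib and tessellated into ~500 triangles; the mesh is rescaled
  uniformly about its insertion point so its area matches the requested
  per-leaf area profile exactly. The default profile is unimodal, peaking
  mid-canopy (about 200 cm² at leaf 6 of 10), following published
  per-leaf areas of mature kale; rosettes with fewer leaves are scaled
  down as younger plants.

What the generator does **not** emulate: petiole/stem geometry as separate
organs, lamina waviness and serration, transverse curvature, and
self-occlusion patterns specific to any real individual. Results that
depend on exact geometry (absolute per-leaf interception) are therefore
scene-specific; the package asserts structural properties (ordering,
correlations, conservation) rather than any published per-leaf values.

## Growth chamber and light sources

`build_chamber()` assembles a single plant-factory cell: a diffusely
reflective bed at $z=0$, optional matte walls, five UV-B bar modules of
twelve point chips each, five red-blue-white (RBW) area panels, and a
virtual sensor at the bed center. The lamp *architecture* (5 × 12 chips,
Lambertian emission truncated at a 60° half-angle, panels ~15 cm above the
canopy top) follows the experimental design being emulated; the chamber
dimensions (600 × 600 mm footprint, emitter plane at 350 mm) are invented
defaults, configurable through `chamber_layout()`.

Emission sampling uses the truncated-cosine law: polar angle density
$\propto \cos\theta\sin\theta$ on $[0, \theta_{max}]$, i.e. CDF
$\sin^2\theta / \sin^2\theta_{max}$, azimuth uniform. Leaf and furniture
optics are band-averaged diffuse reflectance/transmittance pairs
($R + T \le 1$, absorptance $1 - R - T$); the defaults (leaf UV
absorptance 0.94, PAR 0.85; bright bed, dim walls) are plausible for
UV-screened kale epidermis and styrofoam/metal furniture but are stated
defaults, not measurements. `band_average_optics()` converts measured
spectral curves into these pairs, weighting by the source spectrum.

## Monte-Carlo transport

`trace()` is an analog forward tracer: each photon packet carries the full
weight $P_{tot}/n_{rays}$, and every surface hit disposes of the whole
packet — absorbed with probability $1-R-T$, diffusely reflected ($R$) or
transmitted ($T$) with a cosine-weighted new direction. Because weights
never decay, the energy ledger

$$\text{emitted} = \sum_{\text{groups}}\text{absorbed} + \text{escaped} +
\text{terminated}$$

is an exact accounting identity (observed relative error ~$10^{-16}$,
asserted $\le 10^{-12}$). This is also why no Russian-roulette machinery
is needed: a weight-decaying tracer would require roulette to terminate
fairly, while the analog estimator terminates packets naturally and books
the (rare) packets that survive `max_bounces = 10` interactions as
`terminated`. Ray-triangle intersection uses a median-split BVH validated
against brute force on every test mesh; Monte-Carlo standard errors come
from $\ge 10$ batch means.

Spectral handling is per *band* (PAR 400–700 nm, UV 280–400 nm), not per
nanometre: the reported quantities are band-integrated interceptions, and
per-nm tracing would multiply cost without changing them. Per-band optics
absorb the spectral structure via source-weighted averaging.

The virtual sensor is a horizontal disk that tallies downward ray
crossings; its reading is flux/area (W m⁻²). Its default radius (75 mm) is
deliberately larger than a physical quantum-sensor head: bed irradiance is
near-uniform over that area, and the wider disk integrates enough
crossings that a $10^6$-ray reading has ~0.65% Monte-Carlo error, making
the 2% calibration contract a 3σ bound. `calibrate_power()` exploits the
linearity of transport: one pilot trace, then all emitter powers in the
band are scaled by target/reading.

Two ambiguities inherited from the emulated setup are resolved as follows:
nominal powers like "7.1017 W" per RBW plate are treated as
pre-calibration placeholders (calibration makes the absolute value moot),
and per-leaf interception is *absorbed* flux (detector semantics), not
incident flux — an alternative convention would rescale leaf values by
1/absorptance without changing their structure.

## Dosimetry

`band_integrate()` integrates linearly interpolated spectra, clipped to
their support (curves are zero outside it, and bridging a support edge
with a trapezoid would miscount step-edged spectra such as top-hat test
sources). PPFD conversion weights irradiance by $\lambda/(N_A h c)$.
`daily_dose()` is the photoperiod product: 1.0 W m⁻² for 12 h is
43.2 kJ m⁻² d⁻¹.

Biologically effective dose weights the UV spectrum by an action spectrum
normalized to 1 at 300 nm. The default is the analytic (Green)
parameterization of the generalized plant action spectrum, renormalized at
300 nm (the raw analytic form is not unity there); any tabulated spectrum
can be loaded from CSV. Sub-bands follow the 280/315/400 nm convention
(UV-C below 280 nm is empty for the supported sensor range). Because the
tracer works in band-integrated energy, per-leaf biologically effective
doses are obtained by multiplying the traced UV irradiance by the
weighted-to-unweighted dose ratio of the *source* spectrum (~0.26 for the
default Gaussian 310 nm LED model) — exact when the intercepted spectral
shape equals the source shape, which holds here because leaf optics are
flat within the band by construction.

The default UV-B LED model is a Gaussian peaking at 310 nm with σ = 5 nm.
Under the generalized plant action spectrum it yields a biologically
effective fraction of ~0.26; narrow-band sources with less short-wave tail
would give smaller fractions. The package asserts the quadrature itself
(against fine-grid oracles), not any particular published effective-dose
split, which depends on the unpublished measured LED spectrum.

## Chlorophyll fluorescence

`simulate_trace()` renders a standard imaging-fluorometer quenching run (a
5 s measuring-light window, one 0.8 s dark saturating pulse, 17 s
relaxation, 70 s actinic light with five saturating pulses) as a 1-D
mean-ROI trace; `extract_signals()` recovers $F_o$, $F_m$, $F'$, $F'_m$
and `quench_params()` forms

$$F_v/F_m = \frac{F_m - F_o}{F_m},\qquad
NPQ = \frac{F_m - F'_m}{F'_m},\qquad
\Phi_{PSII} = \frac{F'_m - F'}{F'_m}.$$

Extraction choices that were open: $F_o$ is the *mean* over the
measuring-light window (minimum vs mean is unstated in the protocols this
emulates; the mean is unbiased under noise). The pulse maxima are
estimated as the mean over the saturated second half of each pulse window
rather than a pointwise maximum — the fluorescence rise saturates well
before then, and a pointwise max of a noisy plateau is biased upward by
about 1.6σ, which would make the recovered parameters systematically
wrong at any noise level. $F'$ and $F'_m$ come from the *final* (steady
state) light pulse; mid-kinetics pulses are simulated but not used for
headline parameters. All three ratios are invariant to rescaling the
trace, so the arbitrary fluorescence units cancel.

## Synthetic assays and the statistical stage

`synth_assays()` inverts the regression models of the analysis stage into
a generator. Per (plant, leaf): TFC and TPC are linear in leaf order (LO)
and intercepted biologically effective UV dose (UVi, zero for controls,
spanning ~2–10 kJ m⁻² d⁻¹ for treated leaves), with correlated Gaussian
noise; RSA is a saturating logistic
$R_{max}\,\mathrm{logis}(\gamma_0+\gamma_1 LO+\gamma_2 UVi)$, because
radical-scavenging capacity saturates in the youngest leaves. The default
design is 3 plants per treatment with unequal leaf counts (29 control +
27 treated = 56 records), the sample structure of the experiments this
emulates.

The generating coefficients are not free-hand: for standardized targets
$(a_{LO}, a_{UVi})$, response SD $s_y$ and design SDs with predictor
correlation $r$, the raw slopes are $a\,s_y/s_x$ and the residual SD is
$s_y\sqrt{1 - R^2}$ with $R^2 = a_{LO}^2 + a_{UVi}^2 + 2 r a_{LO} a_{UVi}$.
The defaults reproduce the published standardized structure — a dominant
UV effect on flavonoids (0.16 vs 0.80, ratio 5) and near-equal effects on
total phenolics (0.54 vs 0.53) — implying $R^2 \approx 0.74$; a residual
TFC–TPC correlation of 0.27 (shared phenylpropanoid pathway) tops the
pooled TFC–TPC correlation up to ~0.73.

`fit_regression()` wraps ordinary least squares (or nonlinear least
squares for the saturating RSA form) and reports standardized
coefficients $b\,s_x/s_y$; `effect_ratio()` compares their absolute
values. Two numerical notes:

* With orthogonal predictors a standardized coefficient equals the
  marginal Pearson correlation; the suite asserts this identity to
  $10^{-9}$, as well as the equivalence of standardizing before vs after
  fitting.
* Ratio recovery across simulation replicates is assessed as the ratio of
  seed-averaged |standardized coefficients|, not the average of per-seed
  ratios: with a true denominator of ~0.16 and a standard error of ~0.06
  at $n = 56$, the per-seed ratio has a heavy upper tail and its mean is
  inflated several-fold; the ratio of unbiased means recovers the
  generating value to ~1%.

Distribution summaries (`summarize_distribution()`) use type-7
(linear-interpolation) quantiles, central 95% intervals and Tukey
1.5·IQR outlier fences — the quantities a violin/box display of per-leaf
interception encodes. Two-way ANOVA with post-hoc letters is deliberately
out of scope; it is a routine procedure available from base R on the
generated records.

## Reproducibility and problem sizes

Every stochastic stage takes an explicit integer seed: mesh jitter in
`rosette_spec()`, the C++ tracer (one deterministic mt19937_64 stream per
band, derived from the trace seed), R-level emission sampling via
`set.seed()`, and the assay generator. `run_pipeline()` refuses configs
without explicit seeds and writes byte-identical bundles for identical
configs.

Default problem sizes were chosen so the full test suite and the
acceptance script each run in well under a minute of tracing: $10^5$–$10^6$
rays per band (per-leaf irradiances then carry ~1–3% Monte-Carlo error),
$2\times10^6$ pilot rays for calibration, 100-seed simulation loops for the
statistical recovery checks. All are parameters, not limits.

## The command-line question

The package's natural interface is R: every pipeline stage is an exported
function and `run_pipeline()` drives the whole chain from a YAML config.
No shell entry point is shipped; a user wanting one can wrap
`run_pipeline()` in a two-line `Rscript` call, as `scripts/acceptance.R`
does for the headline quantities.

## Known limitations

* No specular/BRDF optics, polarization, fluorescence re-emission or
  participating media; scattering is ideal-diffuse both sides.
* Band-level spectral resolution (finer binning would need per-band
  optics per bin, which the API already permits via additional bands).
* Per-leaf interception values are geometry-specific; only structural
  properties are comparable across scenes.
* The assay generator's linearity in LO and UVi is the analysis model's
  own assumption inverted — it cannot reveal model misspecification, only
  recovery performance under the assumed structure.
* No plant-level random effects: plants differ only through UVi jitter
  and residual noise, matching the fixed-effects analysis stage.
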