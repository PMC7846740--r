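---
title: "From heat pulses to a regional water budget: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From heat pulses to a regional water budget: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standwater)
```

`standwater` estimates the water use of an invading tree stand at four
nested scales — thermocouple, tree, stand, region — and attaches a
monetary value to the regional total. This vignette explains the models at
each scale, the parameters that matter, the numerical choices, and what
the synthetic-data generator does and does not emulate.

## 1. Heat-ratio sap flow

The heat ratio method infers xylem water velocity from the ratio of
temperature rises `v1` (downstream) and `v2` (upstream) measured
equidistant from a heater after a short pulse:

$$V_h = \frac{k}{x}\,\ln\!\frac{v_1}{v_2} \times 3600 \quad [\mathrm{cm/h}]$$

- `k` — thermal diffusivity of fresh sapwood, default `2.5e-3` cm²/s, the
  standard nominal value when wood properties are not measured.
- `x` — heater-to-probe spacing, default 0.5 cm.
- Thermocouple depths default to 0.8 and 1.1 cm below the cambium, the
  band instrumented in the field deployment this package was designed for.

The method's virtue is its behaviour at low and *reverse* flow: the
log-ratio passes smoothly through zero and is antisymmetric
(`Vh(v1,v2) = -Vh(v2,v1)`; implemented as `log(v1) - log(v2)` so the
identity holds to the bit). Samples with non-positive temperature rises
have no defined log-ratio; they are flagged invalid and counted rather
than silently dropped.

**Wound correction.** Drilling kills a cylinder of conducting tissue, so
raw `Vh` underestimates the true velocity. The package applies the
conventional cubic polynomial `Vc = a + b·Vh + c·Vh² + d·Vh³` with
coefficients keyed by wound width, after the published numerical solutions
for the heat-ratio configuration (the linear coefficient grows from ~1.7
at 0.17 cm to ~2.7 at 0.30 cm wound width). Because tabulated coefficient
sets vary between deployments and probe kits, per-site values can be
supplied through the `coefficients` argument; the correction is applied to
the magnitude and re-signed, so reverse flow is corrected symmetrically
and never flipped. By default the wound-corrected velocity is used
directly as sap flux density; a wood-property correction (basic density,
moisture content) would require measurements the deployment did not make,
and is left to the user via custom `coefficients`.

**Tree and stand scaling.** Whole-tree flow integrates velocity over the
sapwood annulus: the ring between the cambium and the visually determined
sapwood depth is split at the midpoint between thermocouple depths, each
annulus carries its probe's velocity, and areas are normalised to the
tree's sapwood area (from the inventory or the fitted OLS allometry on
stem diameter). With partial probe failure the area-weighted mean of the
valid depths is used over the full area; a timestamp where all depths fail
is a gap. Stand transpiration is the stem-size-class weighted mean of
representative tree flows, either per unit canopy (`Q̄/canopy area`,
mm/day over canopy, default 2 m² per tree) or per unit ground
(`Q̄ × stand density`). The representative flow per class defaults to the
mean of the instrumented trees in that class; classes without an
instrumented tree fall back to a flow-on-diameter regression (also
available as an explicit mode), since leaving such a class undefined would
silently bias the weighted sum.

**Daily aggregation.** Timestamps are interval-ending local calendar time.
Gaps up to 2 h are linearly interpolated; days with more than 20% of
intervals still missing are excluded from summaries and counted, because
partial days bias daily totals in a diurnally peaked signal. Negative
daily totals (sustained reverse flow) are physical and retained in the
series, but floored at zero when a rate feeds the upscaling — reverse flow
cannot credit water back to the region. Habitat summaries compute per-tree
period means first, then unweighted means and SDs across trees, so that
large trees do not dominate; values are reported in both L/tree/day and,
through canopy area, mm/day, and the two units are never conflated in one
column.

## 2. Eddy covariance and reference ET

Half-hour fluxes come from the standard open-path chain:

1. **Despiking**: points beyond 6 scaled MADs from the window median are
   replaced by linear interpolation; more than 10% replaced flags the
   window. MAD is used because a spike inflates the SD that would
   otherwise define "spike".
2. **Double rotation**: yaw then pitch so mean crosswind and mean vertical
   wind vanish; wind speed magnitude is preserved sample-by-sample. A
   third (roll) rotation is deliberately not applied, matching
   double-rotation practice.
3. **Lag correction**: each scalar is shifted to the integer-sample lag
   (default window ±2 s) maximising |cross-covariance| with `w`; a scalar
   whose best correlation is below `3/sqrt(n)` is left unshifted and
   flagged, since shifting to a noise peak only manufactures flux.
4. **Fluxes**: `H = ρa·cp·cov(w',Ts')` with air density from the ideal gas
   law at the measured pressure (default 91 kPa, the site mean) and the
   humidity-corrected sonic temperature; `LE` applies the WPL density
   adjustment `(1+μσ)(cov(w',ρv') + (ρv/T)·cov(w',Ts'))`. λ is a linear
   function of temperature (2.501 − 0.002361·T MJ/kg), not a constant,
   because a year-long record spans a large temperature range. ETa per
   interval is `LE·Δt/λ`, clamped at zero for water-budget totals while
   the signed LE is retained in flux outputs. Spectral/frequency-response
   corrections are not implemented (the co-located sonic/IRGA design needs
   no separation correction); this is a known small low bias.

**Reference ET** uses the FAO-56 Penman–Monteith forms: hourly (aerodynamic
coefficient 37 per hour, scaled for half-hour intervals) and daily (900).
Daily ETo defaults to the sum of interval values, matching the
compute-hourly-then-aggregate order. When measured net radiation or soil
heat flux are missing, simple estimators (albedo 0.77·Rs minus a fixed
semi-arid longwave loss; G as the FAO 10%/50% day/night fraction of Rn)
fill in — users with measured Rn/G should supply them. The **crop
coefficient** is the least-squares slope through the origin of daily ETa
on ETo: through the origin because Kc is defined as a ratio, so a free
intercept would absorb exactly the signal being estimated.

**Soil heat flux** adds to the plate reading the energy stored above the
plates, `Cs·(dT/dt)·depth` with `Cs = 1.92·mineral + 2.50·organic +
4.18·θ` MJ/m³/K — the volumetric mix of mineral, organic and water heat
capacities.

## 3. Drivers, upscaling, economics

The driver regression is plain OLS with intercept of a daily response on
exactly five predictors (solar radiation MJ/m²/day, wind m/s, soil
moisture %, VPD kPa, ETo mm/day) — no selection, no interactions — at the
daily grain. Rank deficiency is an error naming the collinear column
rather than a silent drop.

Upscaling is linear: pixel volume `Fc·W·S` litres/day (1 mm over 1 m² is
1 L), summed over valid pixels; annual totals use a fixed 365 (no leap
handling), which makes 3.4 mm/day annualise to exactly 1241 mm/yr.
Invaded area is the footprint of pixels with cover > 0 — the area figure
regional depth is quoted over — with the cover-weighted area also reported
for transparency. The per-pixel output map is in litres/day; a depth label
on a pixel volume (e.g. "826 mm/day/pixel" for a full-cover 225 m² pixel
at 3.67 mm/day) is a unit slip this package does not reproduce. Rasters
are read and written as single-band ESRI ASCII grids (with 0–100 percent
cover autodetected and rescaled); the format is plain text and needs no
geospatial stack.

Economics is deliberately shallow: tariff value is `volume × tariff`
(default US$ 0.00015/m³), and each crop equivalent is the chain
`area = volume / water requirement` (reported to the nearest 10,000 ha,
raw value retained), `tonnage = area × yield`,
`market = tonnage × price range`, `net = market × f(BCR)`. Two net-benefit
conventions circulate in the source literature's own arithmetic, so both
are computed and labelled: `1 − 1/BCR` (default) and `BCR − 1`. No
discounting, price forecasting or control-cost modelling.

## 4. What the synthetic generator does and does not emulate

The generator exists to give every stage an input with known ground truth:

- **Weather**: half-hourly records with a semi-arid diurnal/seasonal
  structure — solar zero at night peaking near noon (clear-sky peak
  1000 W/m²), temperature around a 31 °C annual mean with a 10 °C diurnal
  range, RH inversely coupled to temperature, pressure ~91 kPa, and rain
  only in the July–September season as Bernoulli wet days (p = 0.45) with
  gamma amounts (shape 0.8) whose scale is solved so the expected annual
  total equals the specified 560 mm/yr. The closed-form mean and variance
  of this rain model are what the generator's own Monte-Carlo check tests
  against.
- **Heat pulses**: the exact inverse of the HRM equation — the emitted
  `v1/v2` ratio is `exp(Vh·x/(k·3600))` — with optional additive velocity
  noise, so zero-noise processing must return the prescribed diurnal ×
  seasonal velocity curve to numerical precision.
- **Turbulence**: Gaussian `w',T',q'` mixed by a Cholesky factor of the
  prescribed covariance, then empirically whitened so the *sample* second
  moments match exactly; the prescribed raw covariances are obtained by
  inverting the package's own flux equations at the window means, because
  a sensor sees raw densities while the target is the corrected flux.
  Optional yaw/pitch tilt exercises the double rotation (roll is excluded
  because double rotation cannot correct it).
- **Landscape/inventory**: Bernoulli invasion with Beta(1.1, 4) cover on
  invaded pixels (mean cover ≈ 0.21 over the invaded footprint, the level
  implied by regional mapping of this invasion); stem diameters uniform on
  6–30 cm with sapwood areas from a known linear allometry plus optional
  scatter (the pipeline default scatter puts the fitted R² near the ~0.94
  observed in the field).

What it does **not** emulate: real turbulence spectra (the Gaussian model
has no inertial subrange, so passing flux-recovery tests says nothing
about spectral corrections), storm structure within a day, instrument
drift, energy-balance non-closure (the generator closes it by
construction, which is exactly why the closure invariant is testable), or
spatial autocorrelation of cover. Passing tests therefore demonstrate that
the *algorithms* are correct, not that field uncertainty is small.

## 5. Numerical choices and scales

Degenerate inputs fail loudly and early: non-positive probe geometry,
humidity outside [0, 100], cover outside [0, 1], proportions that do not
sum to 1 (tolerance 1e-9), all-nodata rasters, all-zero ETo, rank-deficient
designs. Determinism is strict: every generator is a pure function of its
seed (the RNG state is saved and restored around each), and the pipeline
derives per-stage sub-seeds from the single config seed, so identical
configs produce byte-identical summary files.

Default problem sizes were chosen so the full test suite runs in seconds:
30-minute windows at 10 Hz (18,000 samples) for flux recovery, 300
synthetic days for the Kc slope, 500 replicates for regression-coverage
calibration, and rasters of order 10²–10³ pixels a side; every identity
being exercised (inversion, linearity, partition additivity) is
scale-free, so nothing is learned by running them larger.

## 6. Known limitations

- Wound-correction coefficients are deployment-specific; the shipped table
  is a sensible default, not a calibration.
- The two-depth radial scheme cannot see velocity profiles steeper than
  its two annuli; probe misalignment is not numerically corrected.
- ETo estimators for missing Rn/G are crude; supply measurements.
- Upscaling assumes one (or monthly, via repeated calls) stand rate across
  the region — no spatial covariates beyond fractional cover.
- The economics is a unit-conversion chain; it inherits every uncertainty
  of its tariff and agronomic inputs.
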