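---
title: "Quantifying mesopelagic habitat extent from gridded ocean projections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mesopelagic habitat extent from gridded ocean projections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesohab)
```

## The model

The mesopelagic ("twilight") zone hosts the deep scattering layer — fishes
and zooplankton that migrate vertically each day and retreat to depth to
avoid visual predators. Its habitable band is not fixed by geography: it is
delimited from above by light and from below by dissolved oxygen.
`mesohab` quantifies that band from gridded physical–biogeochemical ocean
model output.

**Upper boundary.** Downwelling irradiance in a water column is modeled as a
single exponential,

$$I(z) = f_{PAR}\, SW \, e^{-kz},$$

where $SW$ is surface downwelling shortwave (W m⁻²), $f_{PAR} = 0.43$ is the
photosynthetically-available fraction, and $k$ (m⁻¹) is a column-bulk
attenuation coefficient derived from upper-ocean chlorophyll through

$$k = a + b\,\mathrm{Chl}^{\,c},$$

with Chl the 0–100 m depth-averaged chlorophyll (mg m⁻³). Chlorophyll itself
is derived from simulated phytoplankton nitrogen biomass with a constant
Redfield C:N of 106/16 and Chl:C of 0.03. The upper habitat boundary is the
depth at which $I(z)$ falls to $0.0217$ W m⁻² — the irradiance equivalent of
$10^{-1}$ µmol photons m⁻² s⁻¹ under the standard PAR conversion of 4.6 µmol
photons per joule — a light level tied to the daytime ceiling of
light-avoiding mesopelagic animals.

**Lower boundary.** The depth at which dissolved oxygen first crosses below
the hypoxic threshold of 63 mmol m⁻³ (≈ 63 µmol l⁻¹ ≈ 2.0 mg O₂ l⁻¹),
scanning downward with linear interpolation between model levels. Where a
column never becomes hypoxic, the local bottom depth stands in and the cell
is flagged (`lower_is_bottom_fallback`).

**Vertical extent** is the distance between the two boundaries. **Horizontal
habitat area** at a reference depth (default 300 m, near the historical mean
hypoxic-boundary depth) is the summed area of analysis-domain cells whose
interpolated oxygen at that depth exceeds the hypoxic threshold.

The analysis domain is bathymetry- and geometry-based: water cells at least
as deep as the 400 m isobath, within 200 km of the coast, between 34.5°N and
40°N (all bounds inclusive — a deterministic, documented tie rule).

Around this core the package provides the full analysis chain: annual
area-weighted domain means, ordinary least-squares trends, epoch comparisons
(2000–2030 vs 2070–2100, inclusive windows) with Welch *t*-tests, ensemble
mean and spread (member standard deviation), per-cell epoch-difference maps,
and a model-versus-observation evaluation protocol based on co-sampling.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| light threshold | 0.0217 | W m⁻² | 0.1 µmol photons m⁻² s⁻¹ at 4.6 µmol/J |
| oxygen threshold | 63 | mmol m⁻³ | hypoxia threshold for midwater fauna |
| area reference depth | 300 | m | near the historical hypoxic-boundary depth |
| min bottom depth | 400 | m | inshore limit of the analysis domain |
| max offshore distance | 200 | km | offshore limit of the analysis domain |
| latitude bounds | 34.5–40 | °N | Point Conception to Cape Mendocino |
| $f_{PAR}$ | 0.43 | – | PAR fraction of shortwave; configurable |
| $k$–Chl coefficients $(a, b, c)$ | (0.0384, 0.0518, 0.428) | SI | implementer defaults, see below |
| epoch windows | 2000–2030, 2070–2100 | yr | inclusive decadal epochs |
| N² search depth | 100 | m | main thermocline depth |

The $k$–Chl coefficients deserve a caveat. The empirical chlorophyll–
attenuation relationship this stands in for was published without
transferable coefficients, so the defaults here are explicitly implementer
defaults: a plausible pure-water term plus a sublinear chlorophyll
contribution. Every boundary-level test in the package therefore
parameterizes $k$ directly, and no scientific claim made by the tests
depends on these three numbers.

## The synthetic-field generator

`generate_grid()` and `generate_member()` produce a seeded ensemble with the
statistical structure of downscaled regional projections, so the full
pipeline runs and is testable with no external data:

* a meridional coastline with a tanh shelf-slope bathymetry and spherical
  cell areas;
* temperature anchored at ≈ 8.8 °C at 150 m, with a surface-intensified
  linear warming trend (member rates 1.2 / 1.8 / 2.6 °C per century at
  150 m), a seasonal cycle decaying with depth, and AR(1) interannual
  anomalies (ρ = 0.5) — autocorrelated noise is kept deliberately, because
  decadal variability is what makes 20-year trends unreliable, and tests
  should inherit that difficulty;
* a monotone tanh oxygen profile passing through 63 mmol m⁻³ at 290 m with
  a local gradient of 0.23 mmol m⁻³ m⁻¹, an isopleth that deepens offshore,
  and signed linear trends at depth: two deoxygenating members (−24 and −29
  mmol m⁻³ per century at 300 m) and one member with *increasing* subsurface
  oxygen (+10), reproducing the qualitative ensemble-divergence signature in
  which the late-century spread of habitat extent greatly exceeds the
  early-century spread;
* phytoplankton biomass whose magnitude is calibrated so the derived bulk
  attenuation places the light boundary near 187 m under the annual-mean
  shortwave, with a −30 %/century fractional decline imposing roughly
  2 m/century of light-boundary deepening, spring-peaked seasonality, and
  optional marine-heatwave years implemented as multiplicative chlorophyll
  suppression;
* a sinusoidal shortwave climatology (annual mean 200 W m⁻²).

One consequence of the implementer-default attenuation coefficients is that
the calibrated biomass is small in absolute units: the defaults attribute
most attenuation to the pure-water term, so only a little chlorophyll is
needed to place the boundary at 187 m. The generator prioritizes boundary
depths and their rates of change — the quantities the analysis is about —
over the absolute chlorophyll magnitude, which trades off against the
unknowable published coefficients.

With the default ensemble, the domain-mean hypoxic boundary shoals at
≈ 0.6 m yr⁻¹, oxygen at 300 m declines by ≈ 10 mmol m⁻³ between epochs, the
light boundary deepens by ≈ 2.5 m, and vertical extent compresses by tens of
meters in the deoxygenating members while expanding in the oxygenating one.

What the generator does **not** emulate: advection and upwelling dynamics,
water-mass structure, spatially coherent anomaly patterns (yearly anomalies
are spatially uniform), skewed extreme-event distributions, or any
covariance between oxygen and temperature beyond their shared trend. Passing
tests therefore demonstrate that the *analysis machinery* is correct and
well-calibrated — not that any real ocean behaves like the generator.

## Numerical choices

* All depth coordinates are meters, positive down; bathymetry uses the same
  convention.
* Threshold crossings interpolate linearly between the two bracketing
  levels; exact equality at a level returns that level's depth; a profile
  already beyond the threshold at its shallowest wet level returns that
  level with a flag (`hypoxic_at_top`, or undefined for light); fewer than
  two wet levels yields a warning and no crossing.
* Columns where the hypoxic boundary lies *above* the light boundary get
  extent 0 with `fully_compressed = TRUE` rather than omission: zero
  preserves the habitat-lost signal in spatial means, while the flag lets
  users reproduce strict omission. Bottom-fallback columns are included in
  the extent by default (the fallback is part of the lower-boundary
  definition); `omit_fallback = TRUE` switches to the stricter reading in
  which extent is only evaluated where both thresholds are genuinely
  reached. Both paths are tested.
* Upper-ocean integrals are trapezoidal with the shallowest level's value
  extended to the surface; columns shallower than the integration depth are
  integrated to their deepest wet level and logged.
* Fixed-depth extraction interpolates linearly (model levels need not
  coincide with 150 or 300 m) and masks cells whose bottom is shallower
  than the target depth.
* Offshore distance is the haversine great-circle distance (R = 6371 km) to
  the nearest land cell center. Where "offshore" is measured from is a
  genuine ambiguity — coastline assumed here, configurable via the mask
  parameters.
* N² uses centered differences on level midpoints with a linear equation of
  state fallback (α = 2×10⁻⁴ °C⁻¹, β = 7.6×10⁻⁴ psu⁻¹) when only
  temperature is available; a fully unstable column returns its (negative)
  maximum with a warning rather than failing. N² is reported in s⁻² — plots
  elsewhere occasionally label the same quantity in s⁻¹ — and the search
  depth defaults to 100 m (a 150 m variant is sometimes quoted; it is one
  configurable parameter here, not resolved).
* Spatial means are area-weighted by default, with weights renormalized
  over defined cells; unweighted means are available because the choice is
  not always stated in published analyses, and the package's own acceptance
  fixtures use geometries where the two nearly coincide.
* Welch (unequal-variance) two-sided *t*-tests, on annual values: with only
  "a t-test" specified upstream there is no justification for assuming
  equal variances, and annual (not monthly) values match the stated
  "series of yearly values" protocol. Degenerate zero-variance windows
  report an undefined statistic rather than erroring.
* Ensemble spread uses the sample standard deviation (divisor n−1) of the
  members; a population-SD mode exists.
* Evaluation co-samples at the nearest grid cell horizontally (no
  interpolation: observation positioning error dominates at km-scale
  grids), linear in depth, nearest month in time.

## Problem sizes

The demonstration configuration is 3 members on a 16 × 20 cell grid with 45
vertical levels (10 m spacing through the upper 400 m) at monthly resolution
over 2000–2100 — large enough for a nontrivial domain mask and
well-resolved boundaries, small enough to run the full ensemble pipeline in
about a minute. The statistical calibration checks use 500 Monte-Carlo
replicates. These sizes are the package's chosen demonstration scale; all
of them are parameters.

## Known limitations

* The light model is a single column-bulk exponential; layer-resolved or
  spectral optics, diel cycles, and sea-angle effects are out of scope.
* The hypoxic threshold is taxon-agnostic; many mesopelagic taxa tolerate —
  or select — lower oxygen.
* Trend inference is plain OLS; no autocorrelation correction, although the
  generator's AR(1) noise means 20-year sub-period trends wander, which the
  evaluation stage exposes deliberately.
* The NetCDF interchange layer is not part of this package; fields enter as
  in-memory arrays (`field4d`) and results leave as CSV/YAML.
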