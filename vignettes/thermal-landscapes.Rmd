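---
title: "Modelling thermal landscapes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling thermal landscapes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermalscape)
```

`thermalscape` predicts hourly surface temperature and organismal thermal
performance across a fine-scale digital elevation model (DEM), then
summarises the resulting "physiological landscape". This vignette is the
package's own account of the science: the models, their assumptions, the
parameters that matter, and the choices made where the design was
genuinely open.

## 1. Terrain derivatives

Slope and aspect come from Horn's 3×3 finite-difference kernel, the
standard GIS estimator; at centimetre cell sizes it usefully averages
sensor noise. Border cells and neighbours of nodata are **masked rather
than extrapolated**: a one-sided gradient at the DEM edge would
manufacture spurious sun-facing "cliffs" that then show up as hot pixels.
The cost is a one-cell apron of `NA` around the grid and around holes.

Horizon angles are scanned per cell along `n_directions` equally spaced
azimuths (default 32) out to `max_radius` (default 5 m), sampling
elevations bilinearly every cell size and taking the maximum elevation
angle, floored at 0. Rays truncate on leaving the grid or entering
nodata — an open boundary, which slightly overestimates sky openness for
cells near the edge of the mapped area. The scan is the package's one hot
loop and is implemented in C++.

The sky view factor uses isotropic-radiance weighting,
$\mathrm{SVF} = \tfrac1N \sum_i \cos^2 h_i$, so a uniform 45° horizon
gives exactly 0.5. Only the 0–1 definition of SVF is fixed by convention;
the $\cos^2$ weighting is this package's choice (it is the exact result
for an isotropic sky over an unobstructed tilted-free site) and both $N$
and the radius are exposed as parameters.

**Sampling resolution.** One-cell ray stepping cannot resolve horizon
structure inside the first cell, and on very rugged terrain the
discretisation error scales with the local relief. Against a 4× finer
scan the implementation agrees within 2° for 99% of cells on a moderately
rough surface, with worst cases bounded by ~20% of the maximum horizon
angle. At the default 32 directions the azimuthal quantisation is 11.25°;
cast shadows interpolate the horizon linearly between the two adjacent
directions.

Surface roughness `Rq` is the RMS of elevations about the **least-squares
plane** (with a mean-only option). Detrending by a fitted plane rather
than the mean makes the statistic invariant to the overall shore slope,
which seems the right reading of "deviation above the mean plane" for a
tilted shore platform; both conventions are available because published
values do not always say which was used.

## 2. Solar downscaling

Solar position uses the NOAA-style series expansions for declination,
equation of time and the Earth–Sun distance factor; accuracy is well
under 0.5°, ample for hourly steps on centimetre cells. All timestamps
are UTC internally; the CLI converts civil times at the boundary.

Global horizontal irradiance is split into direct and diffuse with the
**Erbs piecewise clearness-index correlation** ($k_t$ = GHI over
extraterrestrial horizontal irradiance; diffuse fraction 1 − 0.09 k_t
below k_t = 0.22, a quartic polynomial to 0.80, 0.165 above). The
correlation family is a substitution — the forcing literature offers
several — so its coefficients live in an argument and alternative splits
can be swapped in without touching the downscaling. DNI is recovered as
(GHI − DHI)/cos z with cos z floored at 0.01 to keep sunrise/sunset
finite; because the synthetic clear-sky generator uses the same floor,
flux closure on a flat open cell holds to machine precision at every
daylight hour.

Per-cell incident shortwave is
$$I = \mathrm{DNI}\cos\theta_i (1-\mathrm{shadow}) + \mathrm{DHI}\cdot\mathrm{SVF}
  + \mathrm{GHI}\,\rho_g (1-\mathrm{SVF}),$$
with $\cos\theta_i$ the beam/normal cosine clamped at zero. The third
term models ground reflection as isotropic surroundings filling the
obstructed part of the hemisphere, with albedo $\rho_g = 0.15$ (dark wet
rock) by default. Multi-bounce terrain reflection and spectral effects
are out of scope.

## 3. The surface heat budget

Each aerially exposed cell solves, at each hour, the steady-state balance

$$\alpha I + \varepsilon\sigma\left[s\,\varepsilon_{sky}T_a^4 + (1-s)T_a^4\right]
 - \varepsilon\sigma T_s^4 - h_c (T_s - T_a) - g_k (T_s - T_{sub}) = 0$$

with $s$ the SVF (sky longwave from the visible sky, terrain longwave at
air temperature from the rest), $\varepsilon_{sky}$ the Swinbank
clear-sky emissivity $9.37\times10^{-6}\,T_a^2$ (K), and temperatures in
kelvin. Defaults, all configurable:

| parameter | default | units | rationale |
|---|---|---|---|
| shortwave absorptivity α | 0.75 | – | dark intertidal rock |
| emissivity ε | 0.95 | – | natural mineral surfaces |
| convection h_c | 5 + 4·u^0.8 | W m⁻² K⁻¹ | forced-convection power law with a still-air floor |
| substrate conductance g_k | 10 | W m⁻² K⁻¹ | shallow rock acting as a damped heat sink |
| substrate temperature | trailing 24 h mean air T | °C | deep rock integrates the recent thermal history |
| ground albedo ρ_g | 0.15 | – | as above |

These functional forms and coefficients are this package's
parameterisation of a standard rock-surface balance; they are the main
place where a user calibrating against loggers should look first.

Numerics: the residual is strictly decreasing in $T_s$, so the root is
bracketed in $[T_a-30, T_a+60]$ K and found by vectorised bisection to an
interval width of 10⁻⁴ K. That width — rather than, say, 0.01 K — is
chosen so the residual at the returned root stays below 0.1 W m⁻² (the
residual slope at the defaults is ≈25 W m⁻² K⁻¹); bisection is cheap
enough that the tighter tolerance is free. A cell whose root escapes the
bracket (physically implausible forcing) is set to `NA` with a warning
rather than clamped.

Assumptions worth stating plainly: the model is **steady-state per hour**
(no thermal inertia within the surface layer; the trailing-mean substrate
term is the only memory), evaporation and tidepool retention are omitted,
submergence follows the still-water tide level with no wave runup, and
rock surface temperature stands in for body temperature — appropriate for
organisms with most of their body in contact with the rock, not for large
or wetted animals.

## 4. Thermal performance curves

The TPC is asymmetric: a Gaussian rise
$\exp[-((T-T_{opt})/2\sigma)^2]$ below the optimum and a quadratic
collapse $1 - ((T-T_{opt})/(T_{opt}-T_{lethal}))^2$ above it, zero at and
beyond the lethal limit. The packaged `generic_intertidal` preset places
the suboptimal/optimal boundary at 21.2 °C, the optimum at 28 °C, the
optimal/sublethal boundary at 30.1 °C and the lethal limit at 35 °C, with
σ = 7 °C giving the broad suboptimal shoulder typical of intertidal
ectotherms; `generic_predator` shifts the curve 3 °C cooler
(optimum 25 °C, lethal 32 °C) for two-species work.

Stress **categories are assigned by temperature interval, not by
performance value**, so category maps are invariant to curve-shape
choices. Boundaries are left-closed/right-open, except "lethal", which is
strictly above the lethal temperature. No acclimatisation or
thermal-history dependence is modelled.

Because the TPC is nonlinear, mean performance over a heterogeneous field
differs from performance at the mean temperature (Jensen's inequality);
`performance_field` plus `relative_performance(mean(T))` makes the gap
directly computable, and the acceptance script reports it.

## 5. Landscape metrics

`RqT` and `RqP` are RMS deviations from the **spatial mean at one
timestamp**, over exposed cells only by default — submerged cells all sit
at water temperature and would dilute the statistic (an
`include_submerged` option exists for sensitivity analysis). Unlike `Rq`
there is no plane detrending: a temperature field has no geometric trend
that must be removed.

Refugia use a strict `<` threshold; an optional minimum-patch-size filter
(4-connected) approximates the fact that a refugium smaller than the
organism is no refugium, but defaults off. Corridor maps intersect one
category's footprint at two hours into persistent/lost/gained sets whose
union is exactly the union of the two footprints.

The two-species interaction map classifies each exposed cell by
favourability to a dominant (predator/competitive dominant) and a
subordinate (prey) species. Favourability defaults to **survivability** —
any non-lethal category — because the ecological question is where the
subordinate can persist at all while the dominant cannot; with the
default presets a uniform 33 °C shore is a wall-to-wall "prey-only
refugium" (lethal to the 32 °C-limited dominant, survivable for the
35 °C-limited prey). Passing
`favourable_categories = c("suboptimal", "optimal")` restricts
favourability to thermally benign cells instead; the four-way partition
logic is unchanged.

Histogram bins are half-open `[e_i, e_{i+1})`; values outside the edge
range are not counted, so conservation of the exposed-cell total holds
exactly when the edges cover the field's range (as the pipeline's
automatic edges do).

## 6. Synthetic data: what it does and does not emulate

The fixture generators define the study conditions for every test:

* **Terrain** — `gaussian_field` synthesises a self-affine surface by
  spectral synthesis (power-law amplitude spectrum, exponent −2 by
  default, the slope of rock-like relief), then rescales the
  plane-detrended relief so its Rq hits the requested set-point exactly
  (the statistic is linear in the field). The demo site uses 2 cm cells
  with Rq = 0.96 m, a realistic roughness for a creviced rocky shore.
  Planes, sinusoids, pits and steps provide closed-form geometry for
  oracle tests.
* **Weather** — clear-sky GHI from a Beer-law transmittance curve
  (τ = 0.75 gives a mid-latitude summer peak of ~920 W m⁻², the right
  order for a cloud-free day), a sinusoidal diurnal air-temperature cycle
  peaking at 15:00 local solar time (default 24 ± 4 °C), constant water
  temperature (16 °C), constant or AR(1) wind (2 m s⁻¹).
* **Tide** — a single harmonic with the 12.42 h principal lunar
  semidiurnal period and 1.5 m half-range.

Real forcing is messier in ways the generators deliberately ignore:
clouds, storms, synoptic air-temperature excursions, mixed tidal
constituents, wave runup, and spatially varying substrate properties.
Passing tests therefore demonstrate that the machinery is correct and the
physics behaves (closure, monotonicity, realistic sun/shade contrast),
not that any particular field site is predicted accurately — that
requires site-specific forcing and logger validation, which are outside
the package.

Each generator draws from a private RNG stream restored afterwards, so
fixtures are reproducible under a seed and adding a generator never
perturbs existing ones.

## 7. Problem sizes and determinism

The shipped demonstrations use a 48×48-cell site (≈1 m² at 2 cm cells)
over one simulated day — small enough that terrain derivatives take well
under a second and the full pipeline about half a second, while still
exhibiting every qualitative feature of interest (double-digit sun/shade
contrast, hour-to-hour corridor turnover, tide masking). Grids of
hundreds of cells on a side remain practical; the horizon scan scales as
cells × directions × (radius/cell size).

Pipelines are deterministic: identical configuration and inputs give
byte-identical metrics tables, and `provenance.json` records input
checksums, the effective-configuration hash and the package version
needed to re-execute a run.

## 8. Known limitations

* No thermal inertia, evaporative cooling, tidepool retention or wave
  splash; temperature extremes on drying rock may be reached faster in
  the model than in nature.
* Rock temperature as body temperature; no organism-specific geometry.
* Heat-budget coefficients are literature-typical, not site-calibrated.
* Open ray boundaries inflate SVF near the DEM edge; the one-cell Horn
  apron removes the outermost ring of cells entirely.
* GeoTIFF geo-tags are not parsed; TIFF rasters need an explicit cell
  size, and the ESRI ASCII grid is the primary interchange format. Hour
  stacks are directories of grids rather than a NetCDF cube.
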