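---
title: "Methods: thermal comfort from low-cost sensor channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal comfort from low-cost sensor channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermocomfort)
```

This vignette documents the models behind the package, the choices made
where the published record leaves the design open, and what the synthetic
validation scenarios do and do not demonstrate.

## The sensing model

A workplace monitor samples a small set of channels every few minutes: air
temperature `ta` (°C), relative humidity `rh` (%), black-globe temperature
`tg` (°C), upward longwave irradiance `lw` (W m⁻²) or equivalently its
brightness temperature `tirt` (°C), a light level `light` (lx), and — only
at semi-outdoor sites — cup-anemometer wind `v` (m s⁻¹). Missing channels
are represented as absent (`NA`), never as sentinel numbers; exactly one of
`lw`/`tirt` needs to be stored, the other is derived by the Stefan–Boltzmann
law.

Three derived quantities feed everything downstream:

* **Vapor pressure** uses the WMO Magnus saturation curve
  (`6.112 · exp(17.62 t/(243.12 + t))` hPa). Any Magnus variant would agree
  to well under 0.1 hPa over indoor temperatures; the WMO constants were
  fixed once and are used identically inside the energy-balance model, so
  humidity is treated consistently end to end.
* **Shortwave irradiance** is a lux-sensor surrogate, `SW = 0.03887 L`,
  with the sensor's saturation handled by assigning 600 W m⁻² strictly
  above 15,000 lx. Implemented literally as calibrated, the mapping jumps
  from 583.05 to 600 W m⁻² across the threshold; exactly 15,000 lx is
  assigned to the linear branch. The cap is applied per sample, before any
  aggregation.
* **Effective wind** floors the channel at 0.1 m s⁻¹: indoor air movement
  is below the starting speed of a cup anemometer (≈0.5 m s⁻¹), and both
  the globe conversion and the energy balance are used with this
  conventional indoor minimum.

## Five routes to mean radiant temperature

`estimate_mrt()` implements five estimates with stable labels:

| label | input channels | formula |
|---|---|---|
| `globe` | `tg`, `ta`, `v` | forced-convection globe equation |
| `ir_l_sphere` | `lw`, `light` | `S_str = F α_k SW + ε_p LW`, `F = 0.167` |
| `ir_l_person` | `lw`, `light` | same, `F = 0.06` |
| `ir_only` | `lw` | brightness temperature |
| `air_temperature` | `ta` | identity |

The globe route uses the ISO 7726 forced-convection form with constant
`1.1·10⁸`, wind exponent 0.6 and diameter exponent 0.4; the default
`globe_spec()` describes a 0.05 m matte-black globe with emissivity 0.95.
Natural-convection corrections for very still air are not modelled — with
the 0.1 m s⁻¹ floor the forced-convection branch is always used. The
inverse, `globe_from_mrt()`, solves the same heat balance for `tg` by
bracketed root finding on [−60, 120] °C (residual < 10⁻⁶); it exists to
manufacture synthetic globe channels and to test the forward route by the
round-trip identity. Under extreme, physically inconsistent inputs the
radiant bracket of the forward equation can go negative; it is then clamped
at absolute zero with a warning rather than returning a complex number.

The radiometric routes assume longwave is isotropic and shortwave arrives
from above, which is why a single upward-pointing sensor pair suffices
indoors; `F = 0.167` weights the upward direction as one face of a sphere,
`F = 0.06` as the overhead view factor of a standing person. In the dark
(`light = 0`) both collapse exactly onto the brightness temperature, since
the body emissivity cancels; with any sunlight the sphere weighting
strictly exceeds the person weighting. A method never silently falls back:
a missing channel is an error, and preference-ordered fallback is an
explicit, recorded choice (`estimate_mrt_fallback()`).

## PET and the three-node energy balance

PET is computed from a steady-state three-node (core / skin / clothing
surface) human heat balance. Heat sources are work metabolism plus a basal
term from sex, age, height and weight; losses are respiration (sensible and
latent), radiation and convection from the bare and clothed body fractions,
skin vapor diffusion, and thermoregulated sweat evaporation. Skin blood
flow and sweat rate follow the standard set-point laws (core set point
36.6 °C, skin 34 °C), giving the familiar behaviour of this model family:
at a comfortable 22 °C the solved skin temperature is around 28 °C, well
below the set point, because vasoconstriction throttles core-to-skin
transport.

The nodal system is solved by damped Newton iteration with a central-
difference Jacobian from the fixed initial state (37, 34, mean(`ta`,
`tmrt`)) °C; convergence requires residuals below 10⁻⁸ W m⁻² (the solver
refuses to return a state worse than 10⁻³ W m⁻²). The solver is
deterministic: identical inputs give bitwise identical states.

PET itself is the air temperature of the reference environment —
`tmrt = PET`, `v = 0.1` m s⁻¹, `vp = 12` hPa, 0.9 clo, 80 W work
metabolism — in which the body, **held at the thermal state solved for the
actual environment**, is in overall (summed three-node) energy balance.
This scalar equivalence criterion is the one used by the modern steady-state
reformulation of the index; the reference vapor pressure of 12 hPa is part
of the PET definition. The root is found by bracketed search (`uniroot`)
over [−60, 90] °C with 10⁻⁴ K tolerance. By construction the identity
`pet(T, 12, T, 0.1) = T` holds at the solver tolerance, which the tests
assert to 0.5 K and observe to ~10⁻⁵ K.

The implementation was cross-checked against an independent coding of the
same equation set in Python (numpy/scipy, `tools/pet_oracle.py`), using a
different solver stack (`fsolve` + `brentq` versus damped Newton +
`uniroot`). Fifty oracle evaluations over `ta ∈ [15,40]`, `tmrt ∈ [15,60]`,
`vp ∈ [5,25]`, `v ∈ [0.1,2]` °C/hPa/m s⁻¹ are frozen in
`tests/testthat/pet-oracle-grid.csv`; the R implementation agrees to better
than 10⁻³ K, and the test requires 0.1 K. The oracle itself reproduces a
published worked example of the same formulation to 0.03 K.

Person parameters (`person_config()`): the standardized subject is male,
35 years, 1.75 m, 75 kg, 0.9 clo, 80 W — light activity in a business
suit. The subject is modelled seated (convection coefficient
`2.67 + 6.5 v^0.67`, radiative area factor 0.696). Clothing below 0.1 clo
is rejected: the cylindrical clothing-layer geometry degenerates as
insulation vanishes, and the index is defined with reference clothing
anyway.

## Stress classification

PET maps to nine ordered classes with boundaries 4, 8, 13, 18, 23, 29, 35,
41 °C. Printed class tables are ambiguous at the boundaries (e.g. "35–41"
next to ">41"); the package fixes the left-closed right-open convention
`[35, 41)` / `[41, ∞)` so that classification is a total, deterministic,
monotone step function. The only deviation this creates from a literal
reading is at the measure-zero boundary values themselves. English labels
are the canonical serialized form; German and French tables are provided
for display purposes.

## Calibration and evaluation

Per-sensor calibration is ordinary least squares of reference on raw
readings (`fit_calibration()`), optionally excluding reference values at or
above a saturation cutoff; it is applied per channel and device at read
time, with out-of-range inputs extrapolated but flagged. Note the
direction: the regression is unbiased when the noise sits on the reference
axis; calibrating a noisy sensor against a much more precise reference (the
climate-chamber setting) is the intended use.

Evaluation statistics are RMSE, MBE, MAE and MSE on differences
**test − reference**, so MBE < 0 means the device under test reads low.
Series on different sampling grids are paired by nearest timestamp within
±2.5 min, the reference series driving the pairing and each test record
used at most once; the instantaneous nearest value is used rather than a
window average. Light-binned difference summaries use the test device's own
light channel with bins {0 lx, (0, 500] lx, (500, ∞) lx} and Tukey boxes
(1.5 IQR whiskers). Stress-frequency summaries report percentages per class
over the full record or the half-open working-hours window [08:00, 18:00)
UTC.

## The synthetic scenario generator

Real two-week paired deployments cannot be reproduced at desk scale, so the
generator manufactures diurnal scenarios with known ground truth. It builds
the physical truth first — a sinusoidal air-temperature cycle, walls
following that cycle with damped amplitude (default 0.7) plus an optional
waste-heat offset, a half-sine window sun pulse, and log-normal semi-outdoor
wind with the 0.5 m s⁻¹ anemometer deadband — and only then derives the
sensor channels from it: the globe channel through the inverse globe
equation and the light channel through the inverse lux conversion. Truth
`T_mrt` is defined through the sphere-weighted flux model, so with noise
switched off both the globe route and the sphere radiometric route recover
the ground truth exactly (to the root-finder tolerance); this is the
pipeline's strongest end-to-end identity. Per-channel Gaussian noise
defaults (`ta` 0.3 K, `rh` 2 %, `tg` 0.3 K, `lw` 5 W m⁻², `light` 5 %
multiplicative) are at low-cost-sensor datasheet scale and configurable; a
paired layout (`generate_reference_pair()`) emulates a device-vs-reference
comparison with a coarser reference grid and configurable bias.

What the generator does **not** emulate: solar geometry and sky radiance
(the sun pulse is a fixed-window half-sine), radiation errors on the
temperature screen, sensor drift and response lags, occupancy and
ventilation events, and cross-channel error correlation. Passing the
synthetic recovery tests therefore demonstrates the correctness of the
computation chain — not field accuracy of any physical device.

## Problem sizes and numerical conventions

The test suite and the acceptance script run at deliberate desk scale: the
oracle grid has 50 points, round-trip identities use 100 random tuples,
bias recovery uses a 14-day scenario (~2000 aligned reference pairs), and
device-vs-reference statistics use a 7-day scenario. Tolerances: globe
round-trip 10⁻⁵ K; PET identity 0.5 K (observed ~10⁻⁵ K); PET oracle
agreement 0.1 K (observed ~10⁻³ K); recovered bias ±0.02 K at ~2000 pairs
(≈3 standard errors of the mean under the default noise). Scenario
timestamps are anchored at an arbitrary fixed date so that fixed seeds give
byte-identical streams; all timestamps are UTC throughout.

## Known limitations

* PET is computed steady-state; transient exposure (entering/leaving hot
  zones) is outside the model.
* The seated posture and mechanical efficiency 0 are fixed; only clothing,
  activity and anthropometrics are configurable.
* The globe inverse and PET searches assume their brackets ([−60, 120] and
  [−60, 90] °C) contain the root; environments outside any plausible
  occupational range error out explicitly rather than extrapolating.
* Calibration is a per-channel linear model; nonlinear sensor responses
  (other than the handled lux saturation) are not modelled.
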