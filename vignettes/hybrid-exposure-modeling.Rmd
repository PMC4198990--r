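---
title: "Hybrid dispersion and kriged-background exposure modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid dispersion and kriged-background exposure modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridex)
```

## The problem

Epidemiologic studies of traffic-related air pollution need exposure
estimates that vary in both space and time: proximity-to-road surrogates
miss the dispersion-driven temporal structure, and sparse central monitors
miss the steep concentration gradients within a few hundred meters of a
highway. `hybridex` implements the hybrid modeling answer to this problem:
locally resolved steady-state Gaussian dispersion of road, stack and area
emissions, added to a regional background estimated by space-time ordinary
kriging of routine monitor observations and scaled by a regional-fraction
field. Hourly concentrations are evaluated on anonymizing receptor
mini-grids near each participant home, interpolated to the true home
distance, and reduced to windowed, source-apportioned exposure metrics.

All pollutants are treated as inert primary tracers in micrograms per cubic
meter; atmospheric chemistry, secondary formation and the downstream health
regression are out of scope.

## Local dispersion

The local solvers share a single Gaussian plume kernel with full ground
reflection. In a frame rotated so transport is along the wind vector, the
concentration per unit emission rate at downwind distance $x > 0$,
crosswind offset $y$ and height $z$ from a release at effective height $h$
is

$$\frac{C}{q} \;=\; \frac{1}{2\pi\, u_{\mathrm{eff}}\, \sigma_y \sigma_z}
  \exp\!\Big(\!-\frac{y^2}{2\sigma_y^2}\Big)
  \left[\exp\!\Big(\!-\frac{(z-h)^2}{2\sigma_z^2}\Big) +
        \exp\!\Big(\!-\frac{(z+h)^2}{2\sigma_z^2}\Big)\right],$$

and zero at or upwind of the source. The dispersion coefficients are the
Briggs open-country curves keyed to Pasquill stability classes A–F. This
class-based scheme is a deliberate simplification relative to the
similarity-theory profiles used by regulatory models (AERMOD, RLINE): it
makes the solver fully specified by the hourly met record alone —
(speed, direction, class) — and therefore exactly testable against closed
forms, at the cost of coarser sensitivity to surface characteristics.
Both coefficients are clamped below at $\sigma_{\min}$ (default 1 m) so
the kernel stays finite arbitrarily close to a source.

Numerical choices:

* **Wind floor.** $u_{\mathrm{eff}} = \max(u, 0.5\ \mathrm{m/s})$. Hours
  with reported speed *below* the floor are treated as calm and produce
  missing values, never zeros; downstream completeness rules then see those
  hours as absent. This mirrors the regulatory convention of refusing to
  trust the steady-plume model in near-calm conditions.
* **Line sources.** Road links carry a uniform per-meter strength and are
  integrated along the polyline by composite trapezoid, doubling the number
  of points until the relative change is below $10^{-3}$ or a hard cap of
  $2^{14}$ points is reached (the result is then returned with a
  `converged = FALSE` flag and a warning). The cap is only reached in the
  corner where a receptor sits within a few meters of a long link under
  very stable classes, i.e. where $\sigma_y$ is at its clamp.
* **Area sources.** Polygons are subdivided into a lattice of equal-rate
  sub-points (midpoints of bounding-box cells inside the polygon, by
  even-odd ray casting), doubling the lattice resolution under the same
  $10^{-3}$ criterion. A receptor inside the polygon is handled by
  excluding sub-points within $\sigma_{\min}$ of it and flagging the
  result.
* **Plume rise.** Stacks use the Briggs final buoyant rise
  $\Delta h = 1.6 F^{1/3} (3.5 x^*)^{2/3}/u$ with
  $F = g v_s d^2 (T_s - T_a)/(4 T_s)$ and the standard $x^*(F)$ split at
  $F = 55$; non-buoyant releases add no rise.
* **Receptors** default to 1.5 m breathing height. Mixing-lid reflections
  are ignored: the near-field, ground-level sources that dominate the
  near-road signal are insensitive to the lid.

Linearity in the emission rate and superposition across sources hold
exactly, which is what makes the mobile / stationary source apportionment
well defined.

## Emissions

Link emissions are emission factors times traffic activity. The
fleet-weighted factor is a two-class mix,
$(1 - \mathrm{CAADT}/\mathrm{AADT})\,EF_{\mathrm{LD}} +
(\mathrm{CAADT}/\mathrm{AADT})\,EF_{\mathrm{HD}}$ (g/veh-km), the minimal
structure expressing the high-diesel / low-diesel contrast; the class count
of real inventories is not resolved here. The hourly line strength in
g/s/m is AADT × month factor × day-type factor × diurnal hour fraction ×
EF × $10^{-3}/3600$.

Stationary annual-average rates are temporally allocated as
`annual × 12·monthly[m] × k·daytype[d] × 24·diurnal[h]`, with day types
collapsed to weekday/Saturday/Sunday and $k$ normalizing day-type
fractions by their natural calendar shares (5/7, 1/7, 1/7). Flat profiles
are the exact identity. Because calendar months have unequal lengths and
day-type counts wobble year to year, exact annual conservation holds for
flat monthly/day-type profiles; strongly non-flat monthly profiles
conserve to roughly the month-length spread (~2%). Spatial surrogate
gridding (`grid_area_emissions()`) is exactly conservative by
construction.

## Regional background

The background at a space-time point is the ordinary-kriging estimate of
the *total* observed concentration at the monitors, multiplied by a
bilinearly interpolated regional-fraction field $r(x, y) \in [0, 1]$
representing the share of the monitored concentration attributable to
sources outside the local domain (derived, in the study design this
package follows, from paired chemical-transport runs with and without
local anthropogenic emissions — those runs themselves are inputs, not
reimplemented).

The covariance is separable exponential,
$C(h, \tau) = \sigma^2 e^{-h/a_s} e^{-\tau/a_t}$ plus a nugget at zero
lag. Choices and defaults:

* Ranges default to $a_s = 15$ km, $a_t = 12$ h — scales appropriate for a
  smooth urban background over a 30 × 40 km domain. Ordinary-kriging
  weights are invariant to the sill's overall scale, so the default sill
  of 1 with a 1% relative nugget yields the same weights for every
  pollutant and lets one solve serve all co-located series;
  `fit_stok_params()` offers a variogram moment-matching fit when
  pollutant-specific parameters are wanted.
* The neighborhood is all sites within ±24 h, capped at the 500 points
  nearest in the scaled distance $h/a_s + \tau/a_t$.
* The nugget sits on the data–data covariance diagonal only, so with zero
  nugget the predictor interpolates the observations exactly; with a
  nugget it smooths (filtered kriging). A singular system is retried once
  with a jittered diagonal, then raised as an error.
* Negative estimates are clamped to zero (physical concentrations).

Whether the ratio should be applied hourly or seasonally, and before or
after kriging, is not settled usage; this package applies a static
per-pollutant ratio multiplicatively to the kriged total, which strips the
local signal embedded in the monitor observations. A known consequence:
very close to a major road the interpolated ratio is pulled down by
near-road lattice nodes, so the *background* category at near-road homes
is mildly conservative there. The recovery tests therefore evaluate the
background at locations away from roads, which is also where the ratio
reading is unambiguous.

## Exposure metrics

Near-road homes get a **mini-grid**: 4 rows × 6 columns of receptors on
50 m centers, rows parallel to the nearest major road (AADT > 25,000
within 300 m), the first row 10 m from the centerline to stay off the
carriageway, columns centered on the perpendicular foot of the home. The
24 receptors never coincide with the home, which anonymizes the location;
the home's hourly value is recovered by reducing each row to its
unweighted 6-receptor mean and interpolating linearly in perpendicular
distance between the two bracketing rows, clamped to the nearest row
outside the 10–160 m range. Homes without a qualifying road use a
**five-point grid** (the home plus ±50 m on each axis) averaged over the
available receptors. Row reduction before interpolation follows from the
gradient geometry: the gradient is perpendicular to the road, so rows are
the informative direction and columns are replicates.

Hourly categories combine as total = mobile + stationary + background; an
hour missing in any component is missing in the total, and apportionment
fractions sum to one wherever the total is positive.

Metrics are windowed means over hour-ending local-standard-time hours
(hour 1 = 00:01–01:00): daily (1–24), a.m. off-peak (1–6), a.m. peak
(7–8), mid-day (9–14), p.m. peak (15–17), p.m. off-peak (18–24). The five
sub-windows partition the day, so a complete daily value equals the
size-weighted mean of the sub-window values. A window is reported only
when at least 70% of its hours are available — so 16/24 fails and 17/24
passes the daily window, and a 3-hour window needs all 3 hours.

Exposure groups follow the recruitment rules with precedence HD > LD > LT:
HD if any road within 150 m exceeds 6,000 CAADT *and* 90,000 AADT; else LD
if any road within 150 m exceeds 90,000 AADT with CAADT below 4,500; else
LT if no road over 25,000 AADT lies within 300 m. Homes near a road in the
unassigned 4,500–6,000 CAADT band, or between 150 and 300 m of a busy
road, are `unclassified` — the definitions genuinely leave that band open.

## Evaluation statistics

`eval_pairs()` drops (never imputes) hours missing in either series and
reports observed/model means, mean bias, mean error, Pearson R and FAC2.
FAC2 bounds are inclusive; a pair with a zero observation counts as within
a factor of two only when the model is also zero. R is reported as
undefined (NA) for fewer than two pairs or zero variance.
`distribution_summary()` uses the standard linear-interpolation percentile
rule.

## The synthetic scenario generator

No study data ship with this package, so `make_scenario()` generates the
full study design with known ground truth:

* a 30 × 40 km planar domain with a high-diesel highway (120,000 AADT,
  8% diesel), a low-diesel highway (100,000 AADT, 3% diesel), a 20,000
  AADT collector and a local road;
* two buoyant stacks and a polygonal airport-type area source with
  annual-average rates of realistic magnitude;
* hourly meteorology with lognormal wind speeds (median 3 m/s, clamped at
  the 0.5 m/s floor), wandering direction, a day/night stability cycle
  (A–D daytime, D–F nighttime) and a diurnal temperature cycle;
* homes recruited into all three exposure groups by construction (HD/LD
  homes 25–140 m from the matching highway, LT homes kilometers from any
  busy road), with stored distances that the classifier must reproduce;
* monitors spread across the domain at least 2 km from the highways, so
  local contributions at monitors are small — the regime in which the
  ratio-times-kriged-observation background is well posed;
* a regional background truth with a ±20% diurnal cycle and a ±5% planar
  spatial gradient (urban backgrounds are nearly uniform at this scale),
  per-pollutant bases spanning the regimes of interest (NOx low, 8
  µg/m³, so roads dominate near-road totals; PM2.5 high, 10 µg/m³, so
  background dominates);
* a regional-fraction lattice computed from the generator's own
  decomposition, r = B̄/(B̄ + L̄) clamped to [0.2, 0.95], with L̄ the
  time-mean local concentration at each node from the package's own
  solvers;
* monitor observations = per-category truth summed, plus additive
  zero-mean Gaussian noise truncated at zero (default SD 5% of each
  series' mean) — the simplest noise model that supports recovery tests.

Every generator is bit-reproducible under a fixed seed, and with zero
noise the observations equal the hybrid truth exactly.

What passing tests on these scenarios do **not** show about real data:
emission factors, traffic counts and meteorology here are internally
consistent by construction, whereas real inventories carry spatial
allocation error; the ratio field is exactly consistent with the truth
decomposition, whereas a transport-model ratio carries model error; and
chemistry (NO–NO₂ conversion, secondary PM) is absent. The test suite
demonstrates the machinery is correct, not that any particular city's
inputs are.

## Problem sizes and defaults used in the shipped checks

The package's own test suite and `scripts/acceptance.R` run scenarios of
48 hours with three homes per group, six monitors and a 6 × 8 ratio
lattice — sizes chosen so a full pipeline pass (dispersion at ~24
receptors per home, one kriging solve per home-hour) completes in tens of
seconds on one core while still exercising multi-day windows, both grid
types and all three groups. Background recovery is judged at five held-out
locations against the known regional truth; model-to-monitor statistics
use leave-one-out backgrounds so a monitor is never kriged from itself.

## Known limitations

* Class-based Briggs curves, no similarity theory, no meander: near-calm
  stable hours are dropped rather than modeled.
* No mixing-lid reflections, deposition, downwash or chemistry.
* The static per-pollutant ratio field under-credits the background
  category within ~100 m of major roads (see above).
* Variogram fitting is a quick moment match intended for synthetic data;
  serious applications should fit and validate their own covariance.
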