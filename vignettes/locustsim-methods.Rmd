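---
title: "Modelling desert locust breeding, development and wind-borne migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling desert locust breeding, development and wind-borne migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locustsim)
```

## The model

`locustsim` simulates *coherent units* of gregarious desert locust
(*Schistocerca gregaria*) — each unit standing for a cohort that breeds,
develops and eventually migrates as one swarm — on a regular geographic
grid with daily time steps. The lifecycle has three compartments, egg,
hopper and adult, linked by environmental gates:

1. **Breeding-site acceptance.** A 0–100 suitability score is predicted
   from three static covariates (elevation, sand content, clay content)
   by a random-forest classifier trained on presence (hopper/band
   reports) versus absence (ecological surveys with no hopper/band
   report within 1 km) points. A site is accepted when a uniform draw
   falls below suitability/100, so the score acts directly as an
   acceptance probability.
2. **Moisture gate.** Egg laying requires recent moisture: any 3-hourly
   record with precipitation > 0 or 0–10 cm soil moisture > 12 mm in
   the closed window 24–48 h before laying. The window is treated as
   closed at both ends and evaluated on the records whose timestamps
   fall inside it; the rule states no endpoint convention, so the
   inclusive reading was adopted.
3. **Egg development.** The daily development percentage is
   `9.41 * exp(-0.00357 * (35.019 - T)^2)` for T in [10, 34] °C and 0
   outside. The rate is accumulated per 3-hourly record (rate/8) until
   the cumulative total first reaches 100 %; the duration is the 1-based
   day index of that record. A hatch is viable only if the duration lies
   in [11, 50] days. Note the curve's optimum (35.019 °C) lies just
   outside its own admissible range; the formula is implemented
   literally, so the maximal rate occurs at 34 °C and the fastest
   possible incubation is ceiling(100/9.375) = 11 days — exactly the
   lower viability bound.
4. **Hopper development.** Rate `0.222 * T - 3.166` on [23, 32] °C,
   same integration, viability window [24, 95] days. Fledging
   additionally requires vegetation: at *every* 16-day NDVI observation
   between hatch and completion the smoothed NDVI must be increasing or
   at/above a regional threshold (0.09 by default, the Red Sea
   calibration; 0.14 has been proposed for the western Sahel). The
   published descriptions of this condition leave open whether it must
   hold at every observation or at least one; the throughout reading was chosen
   because worked accounts of the condition describe NDVI staying above
   the threshold throughout the hopper period, and it is the
   conservative choice for predicting swarm emergence.
5. **Feeding and migration.** From fledging the swarm alternates stays
   and flights. The stay class at a site follows a deterministic table
   over (land-cover group, vegetation state, NDVI trend); the number of
   feeding days is drawn uniformly from the class range (overnight 0,
   short 1–2, medium 2–4, long 4–7). The swarm departs on the morning
   after its last feeding day, flies one day along a wind trajectory
   sampled for its nearest source cell (rigidly translated to the
   departure point), is truncated at the coast if it would cross water,
   and lands at the trajectory's final point.

Temperatures, rainfall and soil moisture enter at 3-hourly cadence; NDVI
at 16-day cadence (the source material mentions both 14- and 16-day
resolutions for the same product; the 16-day MODIS composite cadence is
used). All timestamps are UTC; "local" times are solar times computed
from longitude, not civil time zones, because flight is tied to sunrise
and sunset: swarms fly from 2 h after sunrise to 1 h before sunset,
about 9 h on a 12-h tropical day.

## Vegetation processing

Raw NDVI is smoothed by a Whittaker smoother (second-order difference
penalty, lambda = 1, missing observations weighted 0 and interpolated),
solved exactly as a banded least-squares system. The NDVI *trend* before
a date is classified by fitting continuous piecewise-linear models with
0–3 breaks over the preceding 150 days, break positions aligned to
observation times, selected exhaustively by BIC; adjacent segments with
the same slope sign are merged and the final merged segment decides
INCREASING / CONSTANT / DECREASING, with |slope| ≤ 5e-4 NDVI/day
counting as constant. At ≤ 10 observations per window the exhaustive
search is globally optimal and deterministic, which removes the
initialisation sensitivity of iterative breakpoint estimators; the
5e-4/day flat tolerance is our own choice (a full 0.075 NDVI swing over
150 days) since the three-state classification names a constant state
but no tolerance. Peaks (`find_peaks`) use the m-neighbours rule with
m = 2 (≈ one month either side): a point is a peak when its m neighbours
on each side are lower or equal; plateau runs report their first index
so a flat maximum is counted once.

Vegetation states bin NDVI at 0, 0.15, 0.3, 0.45, 0.6 (half-open
upwards, ≥ 0.6 highest). The stay-class table ships as a reviewable CSV
(`stay_class_table()`). Its constrained cells follow the published
rules: no vegetation or non-vegetated cover means an overnight stop;
long stays occur only on cropland with higher/highest density under
increasing or constant trend. Unconstrained cells are filled by a
monotone scheme — forest and shrubs cap at medium (much forest biomass
is non-consumable wood), sparse vegetation caps at short, and a
decreasing trend demotes one class (not below short) — so the table is
total, monotone in vegetation state, and never rewards a decreasing
trend. Individual unconstrained cells are modelling choices, not
published facts, and can be edited in the CSV.

## Wind trajectories

The simulator *consumes* trajectory ensembles (per source cell, per
day, per realisation, 0.5-h cadence, heights 0–2000 m); it does not do
atmospheric physics. Sampling a flight means choosing the nearest
source lattice cell, drawing a realisation uniformly, and translating
the track rigidly in lon/lat — over sub-20-km offsets the metric
distortion is negligible. Swarms move with the wind at ground speed
equal to wind speed; no airspeed is added.

Heading angles (degrees counterclockwise from East, North = +90°, the
start-to-end vector with longitude scaled by cos latitude) are
summarised by von Mises fits: circular-mean direction, concentration by
the Best–Fisher three-regime approximation of the maximum-likelihood
equation, capped at 1e4, with the mean flagged undefined when the
resultant length falls below 0.01. The angular width reported for a
concentration is the large-kappa spread 2/sqrt(kappa) (4.7° at
kappa = 600); at kappa near 1 this approximation is outside its
validity and is not used.

## The synthetic environment

`synthetic_scenario()` defines the study conditions for all tests: a
3° × 3° semi-arid domain on a 60 × 60 grid (0.05° cells) with a 5-column
eastern ocean margin, 1 September – 29 November 2020, nine trajectory
source cells, 20 realisations per source-day, mean temperature 29 °C
with a 5 °C diurnal amplitude and a 6.5 °C/km lapse, three early-season
rain events, soil moisture decaying with a 5-day e-folding time, NDVI
green-up from mid August to a ~0.45 plateau with November senescence and
0.02 noise, and a steady 5 m/s wind toward the WSW with 1 m/s
Ornstein–Uhlenbeck turbulence. These values were chosen once as a
plausible Horn-of-Africa autumn: they give egg periods of ~12–16 days,
hopper periods of ~35–55 days, a realistic share (well above 30 %) of
attempts failing the early gates, and multi-leg migrations of
~150–250 km/day, without being fitted to any published map.

Trajectory fixtures are advected by explicit Euler steps (0.5 h) through
the parametric wind plus an OU velocity perturbation; vertical spread
scales with the turbulence intensity so calm ensembles collapse to a
single deterministic track. A weak annual harmonic (amplitude 0.01) on
the NDVI baseline keeps noise-free profiles from being exactly flat,
which would otherwise create degenerate plateau peaks under the
lower-or-equal peak rule.

What the generator does *not* emulate: real mesoscale meteorology
(fronts, sea breezes, the ITCZ migration), cloud/QA artefacts in NDVI,
spatially correlated observation noise, survey effort bias, and
trajectory height selection. Passing tests therefore demonstrate the
*mechanics* of the framework — gating, integration, classification,
sampling, bookkeeping — under controlled statistics, not predictive
skill on real upsurge data, which requires the operational covariates
and a trajectory archive.

## Numerical and design choices

- **Grids** are regular geographic lattices; a nominal "1 km" cell is
  1/120°, a "20 km" source spacing 0.18°. Exact metric cells are
  unnecessary at this fidelity. Missing data propagates as NA, never 0.
- **Determinism.** Every stochastic component draws from a stream
  derived from a master seed by a multiplicative hash
  (`derive_seed`), and generators restore the caller's RNG state, so a
  configuration plus seed reproduces histories bit-for-bit.
- **Day counting.** A stage's duration is the 1-based day index of the
  3-hourly record at which cumulative development first reaches 100 %,
  the lay/hatch day counting as day 1; integration at 3-h versus daily
  cadence agrees within a day on constant series.
- **Stage horizons.** Integration gives up after 120 days (egg) / 200
  days (hopper), both beyond the viability windows, so unbounded series
  are never scanned; a stage still developing when the simulated period
  ends terminates the cohort as `simulation-end`, not as a data error.
- **Validation split.** The 80/20 train/validation split is stratified
  by label to avoid degenerate folds on small fixtures; classifier
  probability is the fraction of trees voting presence, and the report
  threshold is 0.5. Duplicate-coordinate ecological records collapse to
  one absence candidate.
- **Ensemble modes.** Fixed-attempt and run-until-k-successes (capped at
  1000 k attempts). Visit maps count landing sites by default;
  overflight counting is available but arrival dates are
  landings-based.
- **Problem sizes.** The shipped tests run the full pipeline at the
  default scenario scale (60 × 60 cells, 9 sources, 20 realisations,
  90 days, 200-cohort ensembles), which a single CPU completes in well
  under a minute per ensemble; operational scale (3000 × 3000 cells,
  3860 sources, 1000 realisations, ~850 days — nearly 3.3 billion
  trajectories) is a configuration change, not an algorithmic one.
- **I/O.** Rasters are read and written as ESRI ASCII grids, gridded
  series and trajectory stores as CSV with JSON sidecar headers
  (17-significant-digit values, so round-trips are bit-exact), surveys
  as plain CSV, histories as JSON-lines, retained forecast tracks as
  GeoJSON.

## Known limitations

Single generation per run (no re-breeding of arriving swarms), no
solitarious–gregarious phase transitions, no swarm splitting/merging or
density dependence, no control interventions, no vegetation depletion
by feeding, no intercontinental crossings (trajectories stop at the
coast), and geographic rather than equal-area cells. The forecast
filter assumes the sighting date is exact and ignores time-of-day.

## A worked run

```{r, eval = FALSE}
env <- fixture_bundle(synthetic_scenario())
h <- run_cohort(c(40.8, 7.6), as.Date("2020-09-07"), env, seed = 5)
h$landings

hs <- run_ensemble(list(lon_min = 40.2, lon_max = 42.4,
                        lat_min = 6.2, lat_max = 8.8),
                   n = 200, as.Date(c("2020-09-01", "2020-09-12")),
                   env, master_seed = 101)
summarise_ensemble(hs, env$scenario$grid)
```
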