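---
title: "Designing wheat ideotypes with a process-based simulator and an evolution strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing wheat ideotypes with a process-based simulator and an evolution strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatideo)
```

## The problem

An *ideotype* is a virtual cultivar: a combination of trait parameter
values expected to maximize yield in a target environment. `wheatideo`
asks what combination of eight winter-wheat traits — phyllochron (`P_h`),
photoperiod response of final leaf number (`P_p`), grain-filling duration
(`G_f`), flag-leaf area (`A_Max`), stay-green (`S_G`), root water uptake
rate (`R_u`), and the photosynthesis (`W_sa`) and senescence (`W_ss`)
responses to water stress — would deliver maximal, *stable* grain yield
around 2050 in two high-yielding wheat countries, the UK and New Zealand,
under rainfed and irrigated management.

The pipeline has three parts, all first-class code:

1. a stochastic daily weather generator with climate-scenario morphing
   (`generate_weather()`, `apply_scenario()`);
2. a daily process-based wheat simulator (`simulate_season()`,
   `simulate_ensemble()`);
3. an evolutionary search with self-adaptive mutation steps over the
   8-trait space with feasibility filtering (`run_easa()`).

## The weather generator

Each site is parameterized by twelve monthly normal sets
(`monthly_normals()`): mean daily Tmin/Tmax with a between-day SD, the
two transition probabilities of a first-order wet/dry Markov chain, a
gamma shape and scale for wet-day amounts, and dry-day/wet-day mean
global radiation with an SD. Years have 365 days (no leap days); series
are continuous across calendar years so seasons sown in October can
mature the following August.

The six built-in sites (`builtin_site()`; ED, LE, RR in the UK and GO,
LI, PU in NZ) are specified in the sources only by *annual* normals
(mean temperature, precipitation, mean radiation). The monthly shapes are
therefore a modelling choice: sinusoidal seasonality with the warm-season
peak in July north of the equator and January south of it, amplitudes
scaled with latitude, winter-skewed precipitation, and radiation reduced
to 60 % on wet days. After shaping, each monthly table is renormalized so
the day-weighted annual aggregates equal the annual targets *exactly* in
expectation; statistical recovery over 100 generated years is within
±0.3 °C, ±5 % precipitation and ±5 % radiation (tested). Daily Tmin and
Tmax share one Gaussian deviation plus a small diurnal-range jitter, so
Tmax ≥ Tmin holds by construction.

A scenario (`climate_scenario()`) is an additive monthly temperature
offset, multiplicative precipitation and radiation factors, a replacement
CO2, and a light-use-efficiency multiplier carried to the crop model. The
built-in 2050 scenario uses country deltas (UK +2.1 °C, radiation
×1.067; NZ +1.9 °C, ×1.011; CO2 541 ppm) with a warm-season-weighted
sinusoidal warming shape whose day-weighted mean equals the country value
exactly; the precipitation change is fixed at ×0.98 since only "a small
decrease (<2 %)" is specified. Uniform-in-month application is the
fallback interpretation of country-level deltas.

## The crop model

**Phenology.** Thermal time is `max(0, (Tmin+Tmax)/2 − T_base)` with
`T_base = 0` °C (standard for wheat). Vernalization progress accumulates
at `max(0, VBEE + VAI·T)` per day and saturates at 1; the final leaf
number is fixed on the saturation day from photoperiod:
`FLN = clamp(L_Min + P_p·max(0, 20 − DL), L_Min, L_Max)`. The 20 h
reference day length and the unit scaling are configurable
(`dl_ref`, `fln_scale` in `sim_config()`); with them, Claire
(`P_p = 0.5`) reaches 13–15 leaves after a UK winter and one extra leaf
per two hours of shorter photoperiod. Anthesis falls two phyllochrons
(configurable `anthesis_lag`) after the flag leaf completes; the grain
fill window and maturity follow at the cultivar's thermal intervals.
Before saturation the provisional FLN is `L_Max`.

**Canopy.** One leaf layer per mainstem leaf; potential layer area ramps
linearly from 0.25·`A_Max` (first leaf) to `A_Max` (flag leaf), each leaf
expanding over one phyllochron. `A_Max` is a per-shoot area; a
`shoot_density` constant (default 125 m⁻²) converts layer areas to
canopy LAI. The default is calibrated so the reference cultivar reaches
an anthesis LAI near 7.7; it is deliberately below field ear densities
because the layer stack retains every leaf produced (no pre-anthesis
senescence is simulated). Post-anthesis senescence starts after a
stay-green delay of `S_G/(1+S_G)` of the grain-fill thermal window and
green area then declines linearly in *effective* thermal time — daily
thermal time multiplied by `1 + (W_ss−1)(1−FW)` — reaching zero no later
than the end of grain fill, which synchronizes total canopy senescence
with the end of filling. Interception follows Beer's law with `k = 0.45`
and PAR = 0.5 × global radiation (both standard, both configurable).

**Soil water.** A cascade of 5-cm layers (210 mm total available water
for the UK profile, 270 mm for NZ; 150 cm deep, equal capacity per
layer), full at sowing. Rain fills layers top-down, excess drains. The
root front advances linearly in thermal time, reaching full depth at
anthesis. Daily extractable supply applies a per-layer fraction falling
linearly from 10 % at the surface to `R_u` % at the root front; a
separate extraction-efficiency curve is not modelled — the fixed 10 %
surface anchor absorbs it. Demand is Priestley–Taylor equilibrium
evaporation times the intercepted fraction; soil evaporation is omitted
(a documented limitation — the available-water semantics absorb it).
`FW = min(1, supply/demand)` and actual uptake is removed from layers in
proportion to their extractable water. Daily water balance closes to
10⁻⁹ mm (tested). Irrigated ("potential") runs pin `FW = 1` rather than
simulating irrigation events.

**Carbon and grain.** Daily biomass is intercepted PAR × RUE modified by
CO2 (`1 + 0.30(CO2−338)/338`), the scenario LUE multiplier, a
temperature factor `clamp(T/10, 0, 1)` (a minimal representation of
temperature limitation), and water stress `1 − W_sa(1−FW)`. At anthesis
the labile carbohydrate pool is fixed at 25 % of biomass; grain number is
`GNEar × ear_fraction × biomass_anthesis` reduced multiplicatively by a
heat term (degree-days of Tmax above `HSGNT` within ±`TT_ANBGF` of
anthesis, scaled by `HSGNR`, capped at 1) and a drought term
(piecewise-linear in the drought stress factor, the mean of FW from
300 °C day before anthesis to the start of grain fill). During filling
the labile pool is released uniformly per unit thermal time; all
post-anthesis assimilate is committed to the grain; grain mass is capped
by grain number × `MaxGW` (0.045 g); if the canopy dies early the
remaining labile pool is forfeited. Yield is reported in t ha⁻¹
(1 g m⁻² = 0.01 t ha⁻¹).

### Calibration

Two constants close the model around the reference cultivar:
`rue_base = 2.7` g DM MJ⁻¹ PAR at the 338 ppm reference, and
`ear_fraction = 0.19`. With them the reference cultivar at the
Rothamsted-parameterized site simulates ≈10.5–11.5 t ha⁻¹, harvest index
≈0.48–0.52, ≈23–24 × 10³ grains m⁻² and anthesis LAI ≈7.4 under baseline
climate — the intended plausibility region. Absolute yields are
calibration outcomes, not validation targets: they depend on these
constants and on the synthetic monthly climatology, and the tests treat
them only as an 8–14 t ha⁻¹ plausibility band.

## The optimizer

`run_easa()` is an elitist evolution strategy over the eight traits with
per-coordinate self-adaptive step sizes. Each step generates 16 offspring
from the parent: step sizes multiply by `exp(τ·N(0,1))` with
`τ = 1/√(2·8)`, clamped to [10⁻³, 0.5] of the range width; values
perturb by `step · N(0,1)` and clamp to the trait bounds; offspring
inherit their evolved steps. Candidates whose yield CV exceeds 10 % or
whose ensemble-mean HI exceeds 0.64 are removed from selection (the HI
ceiling is applied to the ensemble mean, matching how yields are
compared). The next parent is the best feasible candidate among offspring
plus the incumbent — elitism is the reading consistent with running
"until no further improvement". On a generation with no improvement the
incumbent's steps contract by 0.9 (success-rule step control); without
this, failed generations leave the incumbent's steps unadapted and the
search stalls measurably short of known optima. Eight starts are used by
default — one at the reference cultivar, seven uniform in the bounds —
and a run stops when the best feasible yield has improved by less than
10⁻³ t ha⁻¹ for 20 consecutive steps (or at the step cap). All
candidates in a run share one fixed weather realization (common random
numbers), so the objective is deterministic and selection noise-free.

On separable concave test objectives scaled to yield-like magnitude the
search recovers every coordinate of a known optimum to well within 1 % of
its range width (tested); under the irrigated 2050 configuration it
drives the phyllochron to its upper bound, the signature behavior of the
full design study.

## Problem sizes used in tests and the acceptance script

The package's own checks run reduced versions of the full design study:
ensembles of 5–10 seasons in unit tests, and 30-season ensembles with 1–2
optimizer starts and 40–100 steps in the acceptance workflow. These sizes
were chosen as the smallest at which the qualitative behaviors
(feasibility filtering, convergence of `P_h` to its bound, stable CV)
are already unambiguous. `experiment_config()` defaults to the full
100-season, 8-start setting.

## What the generator does and does not emulate

The generator reproduces the *first- and second-order daily statistics*
the crop model consumes: monthly means and variability of temperature and
radiation, wet-day persistence and wet-day amount distributions, and
exact annual aggregates. It does not attempt semi-empirical distribution
fitting, spell-length corrections, inter-variable correlations beyond the
wet/dry radiation split, climatic extremes, or sub-daily structure.
Consequently, passing tests demonstrate correct model mechanics and
faithful scenario arithmetic on statistically realistic inputs — not
agreement with any observed station record. Phenology responses to
warming are sharper here than in calibrated operational models (a uniform
+2 °C advances simulated anthesis by more than the ~11 days such models
report), because leaf appearance is driven purely by thermal time; this
is a known limitation, and treatment comparisons should be read
qualitatively.

## Numerical and degenerate-input conventions

365-day calendar, day-of-year 1-based; percentiles by linear
interpolation between order statistics (`quantile` type 7); CV as
100·SD/mean; seasons that never reach anthesis within 400 days return a
flagged zero-yield result (keeping the optimizer robust to degenerate
parameter draws); evaluator failures mark a candidate infeasible rather
than aborting a run; ties in selection resolve to the first maximum.
Season results are bit-reproducible for fixed inputs, and weather and
optimizer randomness are fully seeded.

## A small worked example

```{r example, eval = FALSE}
site <- builtin_site("RR")
ws <- generate_weather(site, n_years = 11, seed = 42)
cfg <- sim_config(sowing_doy = 293, latitude = 51.80,
                  soil = "rothamsted_210", water_mode = "rainfed")
ens <- simulate_ensemble(cultivar_claire(), ws, cfg)
c(yield = ens$mean_yield, cv = ens$cv_yield, hi = ens$mean_hi)

# ideotype design, reduced scale
site50 <- apply_scenario(site, scenario_2050("UK", lue = 1.10))
ev <- make_yield_evaluator(site50, sim_config(water_mode = "irrigated",
                                              lue = 1.10),
                           n_seasons = 10, weather_seed = 42)
opt <- run_easa(optimization_spec(starts = 1, max_steps = 40), ev, seed = 42)
opt$best$values
```
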