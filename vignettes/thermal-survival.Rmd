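---
title: "Modelling thermal survival of Chinook salmon life stages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling thermal survival of Chinook salmon life stages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salmotherm)
```

salmotherm quantifies how water temperature shapes the survival of three
freshwater life stages of Chinook salmon — adults holding before spawning,
incubating embryos, and juveniles rearing to smolt size — on a common
1 km × 1 day river lattice, so that thermal impacts can be compared across
stages, runs and rivers in one currency: the likelihood of surviving to the
next life stage. This vignette explains the models, the assumptions and the
numerical choices; the README shows the user-facing workflow.

## The temperature field

The basic input is mean daily temperature at integer river kilometres, with
km 0 at the confluence and the axis increasing upstream to an impassable
dam. Monitor records are sparse, so three pre-processing rules build the
grid:

1. **Duplicate averaging.** Multiple recordings at one (km, day) cell are
   arithmetically averaged. Fractional monitor positions are first rounded
   to the grid; a half-km tie rounds away from the confluence (an arbitrary
   but documented choice).
2. **Temporal gap filling.** Within each monitor's observed span, runs of
   missing days *strictly shorter than* 30 days are linearly interpolated
   (`zoo::na.approx`, `maxgap = 29`); 30-day-or-longer runs and
   leading/trailing gaps stay missing. The strict inequality is a literal
   reading of a "less than 30 days" rule.
3. **Spatial interpolation.** Per day, temperature at km *k* is linearly
   interpolated between the nearest monitors bracketing *k* that observe
   that day. There is **no extrapolation**: cells outside the bracketing
   range are masked invalid, and a day with a single observing monitor is
   valid only at that monitor's own km. Masking, rather than nearest-
   neighbour extension, was chosen because downstream warming means an
   extrapolated value would be biased in a direction that depends on which
   end of the river is uncovered; every consumer of the grid treats masked
   cells as "insufficient data", never as zero.

Temporal fill deliberately precedes spatial interpolation; reversing the
order would let a monitor with a long outage silently borrow its
neighbours' seasonal signal.

## The three performance models

**Holding metabolism.** A non-feeding adult's daily maintenance cost is
`B_h = c0 · M^b · e^{DT}` (mgO2 d⁻¹ kg⁻¹) with c0 = 1565.04, b = −0.217,
D = 0.068 °C⁻¹ and adult mass 7.37 kg; path totals convert to MJ kg⁻¹ at
1.358442 × 10⁻⁵ MJ per mgO2. The rate is exactly exponential in
temperature — each additional degree multiplies daily cost by
`exp(0.068) ≈ 1.07` — which is why holding duration and holding temperature
interact so strongly.

**Embryo development and mortality.** Incubation length is the smallest
*n* for which daily increments `0.001044·T + 0.00056` sum to 1; on constant
paths this equals `ceiling(1 / (0.001044·T + 0.00056))` (71 days at 13 °C,
91 at 10 °C), the closed form the tests use as an oracle. Mortality over
those *n* days is `M_T = 1 − exp(−s_T · Σ max(0, T_i − 12))` with
s_T = 0.024 °C⁻¹ d⁻¹. The exceedance is clamped at zero: 12 °C is defined
as the temperature below which there is *no* temperature-dependent
mortality, and without clamping a cold day would spuriously cancel a warm
day's mortality. The development sum assumes non-negative water
temperatures (daily increments then stay positive); sub-zero stream
temperatures are outside the model's domain.

**Juvenile growth.** The growth curve
`Ω = Food · d · (T + T_corr − T_L) · (1 − e^{g(T + T_corr − T_U)})` gives
percent body mass per day for a 1 g fish. `T_corr = 3 °C` shifts the
laboratory-fitted curve cooler, reflecting that field performance peaks
below laboratory optima; `Food = 0.65` scales growth for field ration
levels relative to ad libitum. With these defaults the field-temperature
optimum is 16.02 °C (found by golden-section search to 0.01 °C; the tests
confirm it against a 0.001 °C grid scan). Ω is deliberately *not*
truncated at zero outside the viable range — mass loss is meaningful and
the survival layer handles non-attainment of smolt size.

## From performance to survival surfaces

**Spawning success.** Pixel (k, a) is an adult arriving at km *k* on day
*a*. Per pixel, 1000 replicates draw a spawn date from the Gaussian spawn
phenology truncated at the arrival day (drawn by inverse CDF, rounded to
the day grid, rounded-down draws clamping to the arrival day) and an
initial energy from `N(E_I_mean, E_I_sd)`; holding cost is the summed daily
metabolism between arrival and spawning at that km. Success means
`E_I − E_M − 0.14·E_I − E_H ≥ E_D`: the "enough energy" direction of the
budget, the only direction consistent with the fact that an average
spring-run female at a constant 16 °C can afford 101 whole holding days but
not 110. Gonad cost is 14 % of the *drawn* energy (a proportion of
starting density, not of the population mean), `E_D = 3.4` MJ kg⁻¹ is the
post-spawn carcass energy, and arrivals after the phenology mean ("peak
spawning") spawn immediately at zero holding cost. The scored season is
the 0.5 %–99.5 % quantile range of the arrival and spawn phenologies plus a
30-day buffer on each side — the synthetic analogue of "earliest observed
arrival minus 30 days" on empirical data — and pixels whose holding path
crosses a masked temperature cell are masked.

Each pixel uses a deterministic RNG substream derived from the run seed, so
surfaces are reproducible, independent of evaluation order, and free of
cross-pixel correlation. The tests check the Monte Carlo estimate at fixed
pixels against an independent quadrature oracle (discretized truncated
spawn-date law × closed-form Gaussian energy tail) to 3 percentage points.

**Egg-to-fry survival.** Pixel (k, s) is a redd spawned on day *s*;
survival is `100·(1 − M_T)` over the maturation-determined incubation.
Implementation note: per km the maturation and exceedance sums are
cumulative vectors, so each pixel's duration is a binary search
(`findInterval`) rather than a rescan; a small epsilon guards the
reaches-1 comparison against floating-point ties.

**Smolting success.** Pixel (k, e) is a fry emerging on day *e* at 0.46 g;
mass iterates `M_{t+1} = M_t + (Ω/100)·M_t^{1−α}` (α = 0.338) along the
forward path until 6 g, and survival accumulates `S_{t+1} = S_t·e^{−μ}`
with `μ = X_u·M^f`. Day counting uses the emergence-day-one convention:
the fry is at `M_1` on day 1, so 82 updates put it at smolt size on day
83 — exactly the published days-to-smolt at the optimum, and within 3 % of
the continuous-time solution
`t = (6^α − 0.46^α)/(α·Ω_max/100) ≈ 80.4` days. Pixel values are expressed
relative to the optimum-temperature maximum, so a constant-optimum pixel
scores 100 % by construction. Pixels whose path leaves the grid (or hits
masked data) before smolt size are masked; pixels with complete data where
growth is simply too slow (including non-positive Ω) are masked by default
or scored 0 % via `non_attainment = "zero"` for management scenarios.

### The 62 % question

Under these equations the terminal survival of the optimal trajectory is
**59.2 %** when μ uses the start-of-day mass and **59.5 %** when it uses
the day's updated mass (both conventions are exposed via
`mortality_mass`); integrating μ continuously along the analytic mass
trajectory gives ≈ 59.9 %. The published prediction of 62 % is not
reproducible from the printed parameter set under any of these update
orders, while the companion 83-day figure is reproduced exactly. The
package keeps the faithful computation — start-of-day mass, the stated
dependence of μ on `M_t`, as the default — and reports the value it
actually computes rather than the quoted one. The corresponding acceptance
test is left failing by design, documenting the discrepancy.

Similarly, at a constant 13 °C the printed equations give 18.2 %
egg-to-fry survival (71 incubation days), whereas the source text quotes
"~15 %"; the acceptance check for that sentence is therefore a range test
(15–20 %) rather than an equality.

## Phenology and spatial weighting

Counts are normalized to percentages within each survey year, so a year
with 10 observations weighs as much as one with 1000 — fits are invariant
to rescaling any single year's counts. Gaussian parameters are the
percentage-weighted first and second central moments (population-sd form:
equal weights at days 140 and 160 give sd exactly 10). Method of moments
was chosen over iterative likelihood on binned counts because it is exact
for the Gaussian family on weighted data and directly testable; degenerate
single-support tables require an explicit `sd_override` rather than a
silent guess.

`weight_surface()` draws day and km independently (matching the separate
distribution fits — no joint day × km model), rounds to grid cells, and
keeps draws landing on valid pixels. The number of draws *before*
filtering equals the surface's total pixel count, so weighted and
unweighted summaries rest on comparable replication; invalid draws are
dropped, not redrawn, and a run where fewer than 1 % of draws land on
valid pixels errors out as a distribution/grid mismatch. On multi-year
grids a drawn Julian day is assigned to a uniformly drawn grid year
(phenology replicated across years). The mitigation index — weighted mean
minus unweighted mean — is positive when a population's observed timing
and distribution avoid the river's thermally hostile pixels.

## What the synthetic generator does and does not emulate

`river_scenario()` produces a cosine seasonal cycle plus a linear
upstream-to-downstream warming gradient and i.i.d. Gaussian daily noise.
The cosine is a deliberate idealization: it gives closed-form expected
values at every cell (the zero-noise field equals the deterministic
component exactly), which anchors the round-trip tests of the
interpolation chain. Defaults (12 °C annual mean, ±6–7 °C seasonal
amplitude, peak near day 200, 0.05–0.4 °C km⁻¹ downstream warming over
rivers of 10–30 km) sit in the range of warm, dam-regulated Central
Valley-style streams. Not emulated: flow-driven transients, thermally
stratified holding pools, diel cycles, autocorrelated weather anomalies
and dam-release operations. Passing tests therefore demonstrate the
correctness of the machinery and the qualitative orderings (warmer ⇒
worse incubation; longer holding ⇒ lower spawning success; cool-seeking
distributions ⇒ positive mitigation), not calibrated predictions for any
real river.

Count tables draw `n_obs` observations per year from the scenario's
Gaussians, rounded to the grid and tallied; day draws clamp to 1–365 and
km draws to ≥ 0, so moment recovery is tested away from those boundaries.

## Reproducibility and problem sizes

Every stochastic component takes an explicit seed; pipeline components get
deterministic sub-seeds derived (below 2³¹) from the single master seed in
the configuration, and a rerun of `run_pipeline()` with the same
configuration is byte-identical on disk. The test-suite and example
scenarios use rivers of 10–30 km over one to one-and-a-half years
(roughly 3000–7000 pixels per surface, 1000 energy draws per spawning
pixel) — large enough that every masking rule, buffer and multi-year
code path is exercised, while the full suite stays fast.

## Known limitations

* Holding is assumed to occur at the spawning pixel (holding habitat =
  natal habitat); within-river movement and behavioural thermoregulation
  in cool refugia are not modelled, so predicted holding costs are an
  upper bound where stratified pools exist.
* Migration cost `E_M` is a fixed per-run constant, not a function of
  distance, flow or temperature en route.
* Juvenile results cover natal-ground rearing to the 6 g smolt threshold
  only — no fry/parr emigration strategies and no outmigration survival.
* The Gaussian family is assumed for all phenology and spatial
  distributions; multimodal arrival waves are not represented.
* Model parameters were estimated on populations and conditions that do
  not all match any single river; the framework's comparisons are most
  trustworthy as *relative* statements across stages and scenarios.
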