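# salmotherm

Temperature-dependent survival of freshwater Chinook salmon
(*Oncorhynchus tshawytscha*) life stages, resolved on a 1 km × 1 day river
grid. The package is aimed at quantitative ecologists and water managers who
need to compare thermal impacts **across** life stages, runs and rivers —
for example to decide where cold-water releases below a dam do the most
good — rather than to check a single temperature against a binary
threshold.

## The models

Daily mean stream temperature `T(k, d)` is built from sparse monitor
records by per-monitor temporal gap filling (linear, gaps shorter than 30
days) followed by spatial linear interpolation between bracketing monitors;
cells beyond the outermost observing monitor on a date are masked as
no-data rather than extrapolated.

Three thermal performance models translate that field into per-pixel
likelihoods of success, one per freshwater life stage:

* **Pre-spawn holding adults.** Maintenance metabolism
  `B_h = c0 · M^b · e^{DT}` (c0 = 1565.04 mgO2 d⁻¹ kg⁻¹, b = −0.217,
  D = 0.068 °C⁻¹, M = 7.37 kg) is summed over the holding period and
  converted to MJ kg⁻¹ (1 mgO2 = 1.358442 × 10⁻⁵ MJ). A female entering
  with muscle energy density `E_I ~ N(11.7, 1.0)` MJ kg⁻¹ (spring-run; fall
  run 8.0 ± 1.0) pays migration (`E_M`), gonad formation (14 % of `E_I`)
  and holding (`E_H`) costs; she spawns successfully if the remainder stays
  at or above the post-spawn carcass floor `E_D = 3.4` MJ kg⁻¹. Each pixel
  is scored as the percent of 1000 Monte Carlo replicates (spawn date from
  the phenology, energy from the `E_I` distribution) that succeed.
* **Incubating embryos.** Development accumulates
  `0.001044·T + 0.00056` per day until the sum reaches 1 (emergence); over
  that period mortality is
  `M_T = 1 − exp(−s_T · Σ max(0, T_i − T_crit))` with `s_T = 0.024` and
  `T_crit = 12 °C` — incubation that never exceeds 12 °C has exactly zero
  temperature-dependent mortality.
* **Stream-rearing juveniles.** Growth follows the field-corrected curve
  `Ω = Food · d · (T + T_corr − T_L) · (1 − e^{g(T + T_corr − T_U)})`
  (d = 0.415, g = 0.315, T_L = 1.833 °C, T_U = 24.918 °C, T_corr = 3 °C,
  Food = 0.65), iterated as `M_{t+1} = M_t + (Ω/100)·M_t^{1−α}`
  (α = 0.338) from 0.46 g to the 6 g smolt threshold while size-dependent
  mortality `μ = X_u · M^f` (X_u = 0.00753 d⁻¹, f = −0.27) discounts
  survival daily; pixel scores are relative to the optimum-temperature
  maximum.

Gaussian phenology (Julian day) and spatial (river-km) distributions are
fitted to survey counts (per-year percentage-normalized, weighted method of
moments) and used to sample each surface where and when the life stage is
actually present; comparing the weighted with the unweighted mean (the
*mitigation index*) measures how much a population's observed timing and
distribution buffer it against thermal stress. A synthetic-data module
generates temperature fields, monitor records and count tables with known
ground truth, so the full pipeline is testable without field data.

## Worked example

Scalar model predictions:

```r
library(salmotherm)
optimal_growth_temperature(growth_params())        # 16.02  -> rounds to 16 degC
max_smolt_survival(growth_params())                # $survival 0.592, $days 83
max_holding_days(16)                               # 101 whole days at 16 degC
100 * (1 - embryo_mortality(rep(13, 71)))          # 18.2 % egg-to-fry at 13 degC
```

A full synthetic run: a short, warm river (warmest at the confluence in
July) with a late-arriving fall run that holds, spawns and incubates
upstream in the cold season:

```r
cfg <- list(
  seed = 1,
  river = list(length_km = 12, start = "2013-01-01", end = "2014-06-30",
               mean_annual_temp = 15, seasonal_amplitude = 6, peak_day = 200,
               downstream_warming = 0.4, daily_noise_sd = 0.2),
  monitors = list(kms = c(0, 4, 8, 12)),
  populations = list(
    list(name = "fall_run", run = "fall",
         arrival = list(mean = 320, sd = 20),
         spawn = list(mean = 335, sd = 8),
         emergence = list(mean = 60, sd = 10),
         redds = list(mean = 11, sd = 1),
         rearing = list(mean = 11, sd = 1))
  )
)
run <- run_pipeline(cfg)
dplyr::select(tidy(run), stage, weighting, n, mean, median, mitigation_index)
```

```
       stage  weighting    n mean  median mitigation_index
1   spawning   weighted 3134 81.2  87.400             28.4
2   spawning unweighted 1568 52.7  61.300             28.4
3 egg_to_fry   weighted 3302 99.0 100.000             88.7
4 egg_to_fry unweighted 6546 10.2   0.134             88.7
5   smolting   weighted 6570 95.1  95.645             14.7
6   smolting unweighted 4550 80.4  92.364             14.7
```

Reading the table: if fish occupied every pixel uniformly
(`unweighted`), mean egg-to-fry survival on this river would be 10 % —
most of the year is too warm to incubate. Sampled where and when the
population actually spawns (`weighted`, upstream in late autumn), survival
is 99 %: a mitigation index of +88.7 percentage points. The same holds,
more mildly, for holding adults (+28.4) and rearing juveniles (+14.7) —
the population's phenology and spatial distribution mitigate the river's
thermal stress, and eroding that match (or the cold-water habitat it
depends on) would cost far more survival than the unweighted map suggests.

Useful follow-ups: `autoplot(run$grid)` and
`autoplot(run$populations$fall_run$surfaces$egg_to_fry)` render the
heatmaps; `plot_comparison(run)` draws the weighted vs unweighted violin
comparison; `write_run(run, "out/")` exports every surface, weighted
sample and summary as documented CSV/YAML files. Reintroduction scenarios
(one population's timing on another river's grid and spatial
distributions) are configured with `phenology_from`.

## Package layout

| Surface | Where |
|---|---|
| Synthetic scenarios and survey tables | `river_scenario()`, `generate_true_field()`, `sample_monitor_records()`, `generate_count_table()`, `population_scenario()` |
| Temperature pre-processing | `average_duplicates()`, `fill_temporal_gaps()`, `interpolate_spatial()`, `build_temperature_grid()` |
| Thermal performance models | `holding_metabolic_rate()`, `holding_energy_total()`, `incubation_duration()`, `embryo_mortality()`, `juvenile_growth_rate()`, `optimal_growth_temperature()` |
| Survival surfaces | `spawning_success_surface()`, `egg_to_fry_surface()`, `smolting_success_surface()`, `max_smolt_survival()`, `smolt_trajectory()`, `max_holding_days()` |
| Phenology and space | `normalize_counts()`, `fit_gaussian()`, `gaussian_dist()`, `weight_surface()` |
| Comparison and pipeline | `run_pipeline()`, `summarize_comparison()`, `mitigation_index()`, `plot_comparison()`, `export_heatmap_table()`, `write_run()` |

All tabular data flow as tibbles; grids and surfaces are matrix-backed
objects with `tidy()`, `glance()`, `as_tibble()` and `autoplot()` methods.
Long-format surface CSVs carry columns
`km, date, stage, population, likelihood_pct, valid`; dense matrix exports
use the string sentinel `NA` for masked cells (never 0).
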