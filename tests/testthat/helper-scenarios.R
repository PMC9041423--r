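# shared fixtures, built in code

# grid at a single constant temperature everywhere
flat_grid <- function(temp, n_km = 3, n_days = 120, start = "2013-06-01") {
  kms <- 0:(n_km - 1)
  dates <- seq(as.Date(start), by = "day", length.out = n_days)
  temp_grid(kms, dates, matrix(temp, length(kms), n_days))
}

# deterministic two-season river used across pipeline-level tests
demo_river <- function(length_km = 10, noise = 0, seed = 1) {
  river_scenario(
    river_length_km = length_km,
    start_date = "2013-01-01", end_date = "2014-06-30",
    mean_annual_temp = 12, seasonal_amplitude = 7, peak_day = 205,
    downstream_warming = 0.15, daily_noise_sd = noise, seed = seed
  )
}

# hot river whose coolest pixels are upstream (high km) in winter; used for
# the mitigation property
hot_river <- function() {
  river_scenario(
    river_length_km = 12,
    start_date = "2013-01-01", end_date = "2014-06-30",
    mean_annual_temp = 15, seasonal_amplitude = 6, peak_day = 200,
    downstream_warming = 0.4, daily_noise_sd = 0, seed = 1
  )
}

demo_config <- function(seed = 42) {
  list(
    seed = seed,
    river = list(
      length_km = 10, start = "2013-01-01", end = "2014-06-30",
      mean_annual_temp = 12, seasonal_amplitude = 7, peak_day = 205,
      downstream_warming = 0.15, daily_noise_sd = 0.2
    ),
    monitors = list(kms = c(0, 5, 10)),
    populations = list(
      list(
        name = "spring_run", run = "spring",
        arrival = list(mean = 150, sd = 12),
        spawn = list(mean = 265, sd = 10),
        emergence = list(mean = 20, sd = 10),
        redds = list(mean = 8, sd = 2),
        rearing = list(mean = 6, sd = 2)
      )
    )
  )
}
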