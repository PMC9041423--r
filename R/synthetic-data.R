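#' Synthetic river scenario
#'
#' Describes a dam-regulated river with a smooth seasonal temperature cycle,
#' an upstream-to-downstream warming gradient and daily observation noise.
#' The deterministic component at river-km `k` (0 = confluence, the dam at
#' `river_length_km`) on calendar day `d` is
#' `mean_annual_temp + seasonal_amplitude * cos(2*pi*(jday(d) - peak_day)/365)
#'  + downstream_warming * (river_length_km - k)`.
#'
#' @param river_length_km positive integer, river-km of the dam; the grid
#'   spans km 0..`river_length_km`.
#' @param start_date,end_date inclusive date range of the scenario.
#' @param mean_annual_temp annual mean water temperature, degrees C.
#' @param seasonal_amplitude half peak-to-trough seasonal range, degrees C.
#' @param peak_day Julian day of the warmest water.
#' @param downstream_warming warming per km downstream of the dam
#'   (degrees C per km, >= 0).
#' @param daily_noise_sd sd of i.i.d. Gaussian daily noise, degrees C.
#' @param seed integer seed controlling the noise.
#' @return A `river_scenario` object (a validated list).
#' @export
river_scenario <- function(river_length_km,
                           start_date, end_date,
                           mean_annual_temp = 12,
                           seasonal_amplitude = 6,
                           peak_day = 200,
                           downstream_warming = 0.05,
                           daily_noise_sd = 0.3,
                           seed = 1L) {
  if (!is.numeric(river_length_km) || length(river_length_km) != 1L ||
      river_length_km < 1 || river_length_km != round(river_length_km)) {
    abort("`river_length_km` must be a positive integer.")
  }
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date) || end_date < start_date) {
    abort("`start_date`..`end_date` must be a non-empty date interval.")
  }
  assert_scalar_number(mean_annual_temp, "mean_annual_temp")
  assert_scalar_number(seasonal_amplitude, "seasonal_amplitude")
  assert_scalar_number(peak_day, "peak_day")
  assert_scalar_number(downstream_warming, "downstream_warming")
  if (downstream_warming < 0) abort("`downstream_warming` must be >= 0.")
  assert_scalar_number(daily_noise_sd, "daily_noise_sd")
  if (daily_noise_sd < 0) abort("`daily_noise_sd` must be >= 0.")
  structure(
    list(
      river_length_km = as.integer(river_length_km),
      start_date = start_date, end_date = end_date,
      mean_annual_temp = mean_annual_temp,
      seasonal_amplitude = seasonal_amplitude,
      peak_day = peak_day,
      downstream_warming = downstream_warming,
      daily_noise_sd = daily_noise_sd,
      seed = as.integer(seed)
    ),
    class = "river_scenario"
  )
}

#' Generate the ground-truth temperature field for a scenario
#'
#' Evaluates the scenario's seasonal + gradient model at every (km, day) cell
#' and adds Gaussian daily noise. With `daily_noise_sd = 0` the field equals
#' the deterministic component exactly. Fully reproducible under the
#' scenario's seed; no cell is masked.
#'
#' @param scenario a [river_scenario()].
#' @return A [temp_grid()] covering km 0..length and every day of the range.
#' @export
generate_true_field <- function(scenario) {
  stopifnot(inherits(scenario, "river_scenario"))
  kms <- 0:scenario$river_length_km
  dates <- seq(scenario$start_date, scenario$end_date, by = "day")
  seasonal <- scenario$mean_annual_temp +
    scenario$seasonal_amplitude * cos(2 * pi * (jday(dates) - scenario$peak_day) / 365)
  gradient <- scenario$downstream_warming * (scenario$river_length_km - kms)
  vals <- outer(gradient, seasonal, `+`)
  if (scenario$daily_noise_sd > 0) {
    noise <- with_seed(scenario$seed, {
      matrix(rnorm(length(vals), 0, scenario$daily_noise_sd), nrow = length(kms))
    })
    vals <- vals + noise
  }
  temp_grid(kms, dates, vals)
}

#' Sample sparse monitor records from a temperature field
#'
#' Emulates a network of in-stream temperature loggers: picks the field value
#' at each monitor's km for every day, then drops any (monitor, date) cells
#' covered by `gaps`, giving the long-format record table the gap-filling and
#' interpolation steps consume.
#'
#' @param field a [temp_grid()].
#' @param monitor_kms river-km positions of monitors; must lie on the field's
#'   km axis.
#' @param gaps optional tibble/data.frame with columns `km`, `start`, `end`
#'   (dates, inclusive) describing logger outages.
#' @return A tibble with columns `km`, `date`, `temp_c`, one row per retained
#'   record.
#' @export
sample_monitor_records <- function(field, monitor_kms, gaps = NULL) {
  stopifnot(inherits(field, "temp_grid"))
  monitor_kms <- as.integer(monitor_kms)
  if (length(monitor_kms) == 0L) {
    return(tibble::tibble(km = integer(), date = as.Date(character()), temp_c = numeric()))
  }
  if (!all(monitor_kms %in% field$kms)) {
    abort("All `monitor_kms` must lie on the field's km axis.")
  }
  rows <- match(monitor_kms, field$kms)
  out <- tibble::tibble(
    km = rep(monitor_kms, each = length(field$dates)),
    date = rep(field$dates, times = length(monitor_kms)),
    temp_c = as.vector(t(field$values[rows, , drop = FALSE]))
  )
  if (!is.null(gaps) && nrow(gaps) > 0L) {
    gaps <- tibble::as_tibble(gaps)
    drop <- rep(FALSE, nrow(out))
    for (i in seq_len(nrow(gaps))) {
      drop <- drop | (out$km == gaps$km[i] &
                        out$date >= as.Date(gaps$start[i]) &
                        out$date <= as.Date(gaps$end[i]))
    }
    out <- out[!drop, , drop = FALSE]
  }
  dplyr::arrange(out, .data$km, .data$date)
}

#' Synthetic survey count tables
#'
#' Draws `n_obs` observations per year from `Normal(mean, sd)`, rounds them to
#' the 1-day or 1-km grid and tallies counts, emulating phenology (Julian day)
#' or spatial (river-km) survey tables. Day values are clamped to 1..365 and
#' km values to >= 0 so tallies stay on the grid.
#'
#' @param mean,sd Gaussian location/scale on the axis (days or km); `sd > 0`.
#' @param n_obs positive integer, observations per year.
#' @param n_years number of survey years.
#' @param seed integer seed.
#' @param axis `"day"` for a phenology table (column `julian_day`) or `"km"`
#'   for a spatial table (column `river_km`).
#' @return A tibble with columns `julian_day` (or `river_km`), `count`,
#'   `year`.
#' @export
generate_count_table <- function(mean, sd, n_obs, n_years = 1L, seed = 1L,
                                 axis = c("day", "km")) {
  axis <- match.arg(axis)
  assert_scalar_number(sd, "sd", positive = TRUE)
  if (!is.numeric(n_obs) || length(n_obs) != 1L || n_obs <= 0) {
    abort("`n_obs` must be a positive integer.")
  }
  axis_col <- if (axis == "day") "julian_day" else "river_km"
  out <- purrr::map_dfr(seq_len(n_years), function(y) {
    draws <- with_seed(derive_seed(seed, y), round(rnorm(n_obs, mean, sd)))
    draws <- if (axis == "day") pmin(pmax(draws, 1), 365) else pmax(draws, 0)
    tab <- table(draws)
    tibble::tibble(
      !!axis_col := as.integer(names(tab)),
      count = as.integer(tab),
      year = y
    )
  })
  out
}

#' Synthetic population scenario
#'
#' Bundles the Gaussian phenology (arrival, spawning, emergence timing in
#' Julian days) and spatial (redd and rearing river-km) parameters used to
#' generate a population's survey tables.
#'
#' @param name population label (e.g. `"spring_run"`).
#' @param run `"spring"` or `"fall"`, selecting the energy-budget preset.
#' @param arrival_mean,arrival_sd adult arrival timing (Julian days).
#' @param spawn_mean,spawn_sd spawn timing (Julian days);
#'   `arrival_mean < spawn_mean` is required.
#' @param emergence_mean,emergence_sd fry emergence timing (Julian days).
#' @param redd_mean_km,redd_sd_km redd (spawning) locations (river-km).
#' @param rearing_mean_km,rearing_sd_km juvenile rearing locations (river-km).
#' @param n_fish_per_survey observations per survey year.
#' @param n_years survey years.
#' @param seed integer seed.
#' @return A `population_scenario` object.
#' @export
population_scenario <- function(name = "population", run = c("spring", "fall"),
                                arrival_mean, arrival_sd,
                                spawn_mean, spawn_sd,
                                emergence_mean, emergence_sd,
                                redd_mean_km, redd_sd_km,
                                rearing_mean_km, rearing_sd_km,
                                n_fish_per_survey = 500L, n_years = 3L,
                                seed = 1L) {
  run <- match.arg(run)
  if (arrival_mean >= spawn_mean) abort("`arrival_mean` must precede `spawn_mean`.")
  for (s in c(arrival_sd, spawn_sd, emergence_sd, redd_sd_km, rearing_sd_km)) {
    if (!is.finite(s) || s <= 0) abort("All scenario standard deviations must be > 0.")
  }
  if (n_fish_per_survey <= 0) abort("`n_fish_per_survey` must be positive.")
  structure(
    list(
      name = name, run = run,
      arrival_mean = arrival_mean, arrival_sd = arrival_sd,
      spawn_mean = spawn_mean, spawn_sd = spawn_sd,
      emergence_mean = emergence_mean, emergence_sd = emergence_sd,
      redd_mean_km = redd_mean_km, redd_sd_km = redd_sd_km,
      rearing_mean_km = rearing_mean_km, rearing_sd_km = rearing_sd_km,
      n_fish_per_survey = as.integer(n_fish_per_survey),
      n_years = as.integer(n_years),
      seed = as.integer(seed)
    ),
    class = "population_scenario"
  )
}

#' Generate all survey tables for a population scenario
#'
#' @param scenario a [population_scenario()].
#' @return A named list of count tables (`arrival`, `spawning`, `emergence`
#'   on Julian day; `redds`, `rearing` on river-km).
#' @export
generate_survey_tables <- function(scenario) {
  stopifnot(inherits(scenario, "population_scenario"))
  gen <- function(mean, sd, axis, idx) {
    generate_count_table(mean, sd,
      n_obs = scenario$n_fish_per_survey, n_years = scenario$n_years,
      seed = derive_seed(scenario$seed, idx), axis = axis
    )
  }
  list(
    arrival = gen(scenario$arrival_mean, scenario$arrival_sd, "day", 1L),
    spawning = gen(scenario$spawn_mean, scenario$spawn_sd, "day", 2L),
    emergence = gen(scenario$emergence_mean, scenario$emergence_sd, "day", 3L),
    redds = gen(scenario$redd_mean_km, scenario$redd_sd_km, "km", 4L),
    rearing = gen(scenario$rearing_mean_km, scenario$rearing_sd_km, "km", 5L)
  )
}
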