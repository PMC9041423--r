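#' Average duplicate monitor records per river-km cell
#'
#' When more than one temperature recording is present for the same river
#' kilometre and date (co-located loggers, or distinct monitors rounding to
#' the same integer km), the cell value is their arithmetic mean. Monitor km
#' positions are rounded to the nearest integer km first; ties round half
#' away from the confluence.
#'
#' @param records tibble with columns `km`, `date`, `temp_c`.
#' @return A tibble with one row per (km, date), `temp_c` averaged.
#' @export
average_duplicates <- function(records) {
  records <- tibble::as_tibble(records)
  records$km <- round_km(records$km)
  records$date <- as.Date(records$date)
  dplyr::summarise(
    dplyr::group_by(records, .data$km, .data$date),
    temp_c = mean(.data$temp_c),
    .groups = "drop"
  )
}

#' Fill short temporal gaps in monitor series
#'
#' For each monitor, days between its first and last observation with no
#' record form gaps. Internal gaps strictly shorter than `max_gap_days` are
#' filled by linear interpolation between the flanking observations; gaps of
#' `max_gap_days` or more, and days before the first / after the last
#' observation, stay missing. Records already present are returned unchanged.
#'
#' @param records tibble with columns `km`, `date`, `temp_c` (one value per
#'   (km, date); apply [average_duplicates()] first if needed).
#' @param max_gap_days gaps of this many days or longer are left unfilled
#'   (default 30, i.e. "gaps of less than 30 days" are interpolated).
#' @return A tibble `km`, `date`, `temp_c` including the filled days.
#' @export
fill_temporal_gaps <- function(records, max_gap_days = 30L) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L || all(is.na(records$temp_c))) {
    abort("Cannot gap-fill an all-missing record set.")
  }
  records$date <- as.Date(records$date)
  filled <- dplyr::group_modify(
    dplyr::group_by(records, .data$km),
    function(df, key) {
      df <- df[!is.na(df$temp_c), , drop = FALSE]
      if (nrow(df) == 0L) {
        abort(sprintf("Monitor at km %s has no observed values.", key$km))
      }
      days <- seq(min(df$date), max(df$date), by = "day")
      temps <- rep(NA_real_, length(days))
      temps[match(df$date, days)] <- df$temp_c
      if (length(days) > 1L) {
        temps <- zoo::na.approx(temps,
          x = as.numeric(days), maxgap = max_gap_days - 1L, na.rm = FALSE
        )
      }
      tibble::tibble(date = days, temp_c = as.numeric(temps))
    }
  )
  out <- dplyr::ungroup(filled)
  out <- out[!is.na(out$temp_c), c("km", "date", "temp_c")]
  dplyr::arrange(out, .data$km, .data$date)
}

#' Spatially interpolate monitor series onto the 1 km grid
#'
#' For each date, the temperature at river-km `k` is linearly interpolated
#' between the nearest monitors observing that date that bracket `k`. No
#' extrapolation is performed: cells upstream of the uppermost or downstream
#' of the lowermost observing monitor on a date are masked invalid, and a
#' date with a single observing monitor yields a valid value only at that
#' monitor's own km.
#'
#' @param records tibble `km`, `date`, `temp_c` (deduplicated, gap-filled).
#' @param river_length_km extent of the grid; km axis is 0..`river_length_km`.
#' @param dates optional date axis; defaults to the full daily range of the
#'   records.
#' @return A [temp_grid()] with the interpolation mask.
#' @export
interpolate_spatial <- function(records, river_length_km, dates = NULL) {
  records <- tibble::as_tibble(records)
  if (!is.numeric(river_length_km) || river_length_km < 0) {
    abort("`river_length_km` must be a non-negative number.")
  }
  if (nrow(records) == 0L) abort("No monitor records to interpolate.")
  records$km <- round_km(records$km)
  records$date <- as.Date(records$date)
  if (any(records$km < 0 | records$km > river_length_km)) {
    abort("Monitor positions must lie within 0..river_length_km.")
  }
  kms <- 0:as.integer(river_length_km)
  if (is.null(dates)) {
    dates <- seq(min(records$date), max(records$date), by = "day")
  } else {
    dates <- sort(as.Date(dates))
  }
  vals <- matrix(NA_real_, nrow = length(kms), ncol = length(dates))
  by_date <- split(records[c("km", "temp_c")], factor(as.character(records$date)))
  for (d in names(by_date)) {
    j <- match(as.Date(d), dates)
    if (is.na(j)) next
    obs <- by_date[[d]]
    obs <- obs[!is.na(obs$temp_c), , drop = FALSE]
    if (nrow(obs) == 0L) next
    if (nrow(obs) == 1L) {
      vals[match(obs$km, kms), j] <- obs$temp_c
    } else {
      vals[, j] <- approx(obs$km, obs$temp_c, xout = kms, rule = 1)$y
    }
  }
  temp_grid(kms, dates, vals)
}

#' Build the temperature grid from raw monitor records
#'
#' Runs the full pre-processing chain: duplicate averaging, temporal gap
#' filling per monitor, then spatial linear interpolation onto the
#' 1 km x 1 day grid (temporal fill deliberately precedes spatial
#' interpolation).
#'
#' @inheritParams interpolate_spatial
#' @inheritParams fill_temporal_gaps
#' @return A [temp_grid()].
#' @export
build_temperature_grid <- function(records, river_length_km,
                                   max_gap_days = 30L, dates = NULL) {
  records |>
    average_duplicates() |>
    fill_temporal_gaps(max_gap_days = max_gap_days) |>
    interpolate_spatial(river_length_km = river_length_km, dates = dates)
}

#' Read monitor records from CSV
#'
#' Expects columns `km` (numeric river-km), `date` (ISO-8601) and `temp_c`.
#'
#' @param path file path.
#' @return A tibble of monitor records.
#' @export
read_monitor_csv <- function(path) {
  readr::read_csv(path,
    col_types = readr::cols(
      km = readr::col_double(),
      date = readr::col_date(),
      temp_c = readr::col_double()
    )
  )
}
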