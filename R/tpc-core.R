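#' Maintenance metabolism of a holding adult
#'
#' Evaluates `B_h = c0 * M^b * exp(D * T)`, the daily energy use of a
#' non-feeding adult holding at temperature `T`, in mgO2 per day per kg.
#' Strictly increasing in temperature. Vectorized over `T`.
#'
#' @param T water temperature, degrees C.
#' @param p a [holding_params()] bundle.
#' @return Metabolic rate(s), mgO2 d^-1 kg^-1.
#' @export
holding_metabolic_rate <- function(T, p = holding_params()) {
  stopifnot(inherits(p, "holding_params"))
  if (any(!is.finite(T))) abort("`T` must be finite.")
  p$c0 * p$M_adult^p$b * exp(p$D * T)
}

#' Total holding energy cost over a temperature path
#'
#' Sums the daily maintenance metabolism along a day-indexed temperature path
#' and converts from mgO2/kg to MJ/kg via the oxycalorific coefficient.
#' Additive over path concatenation; a zero-day path costs 0.
#'
#' @param temps day-indexed temperature path, degrees C (may be empty).
#' @param p a [holding_params()] bundle.
#' @return Total holding cost, MJ per kg.
#' @export
holding_energy_total <- function(temps, p = holding_params()) {
  stopifnot(inherits(p, "holding_params"))
  if (length(temps) == 0L) return(0)
  if (any(!is.finite(temps))) {
    abort("Holding path contains missing temperatures (insufficient data).")
  }
  sum(holding_metabolic_rate(temps, p)) * p$t_step * p$oxycal
}

#' Incubation duration from the maturation sum
#'
#' The embryo accumulates a daily development increment
#' `dev_slope * T_i + dev_intercept`; emergence occurs on the first day `n`
#' on which the cumulative sum reaches 1. If the path (or the
#' `max_incubation_days` cap) is exhausted first, or a missing temperature is
#' hit before emergence, `NA` is returned so the caller can mask the pixel.
#'
#' @param temps temperature path starting on the spawn day, degrees C.
#' @param p an [embryo_params()] bundle.
#' @return Integer number of days to emergence, or `NA` when the data are
#'   insufficient.
#' @export
incubation_duration <- function(temps, p = embryo_params()) {
  stopifnot(inherits(p, "embryo_params"))
  if (length(temps) == 0L) abort("Incubation path must be non-empty.")
  n_max <- min(length(temps), p$max_incubation_days)
  inc <- p$dev_slope * temps[seq_len(n_max)] + p$dev_intercept
  bad <- which(!is.finite(inc))[1]
  dev <- cumsum(ifelse(is.finite(inc), inc, 0))
  n <- which(dev >= 1)[1]
  if (is.na(n) || (!is.na(bad) && bad <= n)) return(NA_integer_)
  as.integer(n)
}

#' Temperature-dependent embryonic mortality
#'
#' `M_T = 1 - prod(exp(-s_T * max(0, T_i - T_crit)))` over the incubation
#' path: mortality accrues only on days above `T_crit`, so any path that
#' never exceeds 12 degrees C has exactly zero temperature-dependent
#' mortality. Order of days does not matter (product form), and mortality is
#' non-decreasing in every day's temperature.
#'
#' @param temps temperature path of the incubation period, degrees C.
#' @param p an [embryo_params()] bundle.
#' @return Mortality probability in \[0, 1\].
#' @export
embryo_mortality <- function(temps, p = embryo_params()) {
  stopifnot(inherits(p, "embryo_params"))
  if (length(temps) == 0L || any(!is.finite(temps))) {
    abort("Incubation path must be non-empty and fully observed.")
  }
  exceed <- pmax(0, temps - p$T_crit)
  1 - exp(-p$s_T * sum(exceed))
}

#' Mass-standardized juvenile growth rate
#'
#' The corrected thermal growth curve
#' `Omega = Food * d * (T + T_corr - T_L) * (1 - exp(g * (T + T_corr - T_U)))`
#' in percent body mass per day for a 1 g fish. Values outside the viable
#' range are negative (mass loss) and deliberately not truncated; the smolt
#' trajectory handles non-attainment. Exactly linear in `Food`. Vectorized
#' over `T`.
#'
#' @param T field water temperature, degrees C.
#' @param p a [growth_params()] bundle.
#' @return Growth rate(s) Omega, percent mass per day per 1 g fish.
#' @export
juvenile_growth_rate <- function(T, p = growth_params()) {
  stopifnot(inherits(p, "growth_params"))
  if (any(!is.finite(T))) abort("`T` must be finite.")
  Te <- T + p$T_corr
  p$Food * p$d * (Te - p$T_L) * (1 - exp(p$g * (Te - p$T_U)))
}

#' Field temperature maximizing juvenile growth
#'
#' Finds the (field) temperature at which the corrected growth curve peaks,
#' by golden-section search on the interval where growth is non-negative.
#' With the default 3 degree C correction the optimum rounds to 16 degrees C.
#' Invariant to `Food` (a positive scaling).
#'
#' @param p a [growth_params()] bundle.
#' @param tol search tolerance, degrees C.
#' @return Optimal field temperature, degrees C.
#' @export
optimal_growth_temperature <- function(p = growth_params(), tol = 0.01) {
  stopifnot(inherits(p, "growth_params"))
  lower <- p$T_L - p$T_corr
  upper <- p$T_U - p$T_corr
  optimize(function(T) juvenile_growth_rate(T, p),
           interval = c(lower, upper), maximum = TRUE, tol = tol)$maximum
}
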