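#' Adult holding metabolism parameters
#'
#' Parameters of the exponential maintenance-metabolism model for pre-spawn
#' holding adults, `B_h = c0 * M^b * exp(D * T)` (mgO2 per day per kg), with
#' daily costs converted to MJ per kg via the oxycalorific coefficient.
#' Defaults are the published Chinook salmon values: `c0` normalized to a
#' daily time step, mass exponent `b` and temperature exponent `D` from
#' salmonid metabolic studies, and a 7.37 kg average adult female.
#'
#' @param c0 daily normalization constant, mgO2 d^-1 kg^-1.
#' @param b mass exponent of maintenance (unitless).
#' @param D temperature exponent of maintenance, per degree C.
#' @param M_adult adult mass, kg.
#' @param t_step time step, days.
#' @param oxycal MJ per mgO2 (1 mgO2 = 1.358442e-5 MJ).
#' @return A `holding_params` object.
#' @export
holding_params <- function(c0 = 1565.04, b = -0.217, D = 0.068,
                           M_adult = 7.37, t_step = 1,
                           oxycal = 1.358442e-5) {
  assert_scalar_number(c0, "c0", positive = TRUE)
  assert_scalar_number(b, "b")
  assert_scalar_number(D, "D")
  assert_scalar_number(M_adult, "M_adult", positive = TRUE)
  assert_scalar_number(t_step, "t_step", positive = TRUE)
  assert_scalar_number(oxycal, "oxycal", positive = TRUE)
  structure(
    list(c0 = c0, b = b, D = D, M_adult = M_adult, t_step = t_step, oxycal = oxycal),
    class = "holding_params"
  )
}

#' Embryo incubation parameters
#'
#' Parameters of the temperature-dependent embryonic mortality model and the
#' degree-day-style maturation sum that sets the incubation duration.
#' Mortality accrues only on days warmer than `T_crit` (12 degrees C, the
#' temperature below which there is no temperature-dependent mortality) at
#' slope `s_T`. Development accumulates daily increments
#' `dev_slope * T + dev_intercept`; the embryo emerges when the sum reaches 1.
#'
#' @param s_T mortality slope above `T_crit`, per degree C per day.
#' @param T_crit no-mortality threshold, degrees C.
#' @param dev_slope,dev_intercept maturation-rate coefficients (per degree C
#'   per day; per day).
#' @param max_incubation_days scan cap for pathologically cold paths; hitting
#'   it is reported as insufficient data, not emergence.
#' @return An `embryo_params` object.
#' @export
embryo_params <- function(s_T = 0.024, T_crit = 12.0,
                          dev_slope = 0.001044, dev_intercept = 0.00056,
                          max_incubation_days = 365L) {
  assert_scalar_number(s_T, "s_T", positive = TRUE)
  assert_scalar_number(T_crit, "T_crit")
  assert_scalar_number(dev_slope, "dev_slope", positive = TRUE)
  assert_scalar_number(dev_intercept, "dev_intercept")
  assert_scalar_number(max_incubation_days, "max_incubation_days", positive = TRUE)
  structure(
    list(
      s_T = s_T, T_crit = T_crit,
      dev_slope = dev_slope, dev_intercept = dev_intercept,
      max_incubation_days = as.integer(max_incubation_days)
    ),
    class = "embryo_params"
  )
}

#' Juvenile growth and smolting parameters
#'
#' Parameters of the corrected juvenile growth curve
#' `Omega = Food * d * (T + T_corr - T_L) * (1 - exp(g * (T + T_corr - T_U)))`
#' (percent body mass per day per 1 g fish) and of the daily mass/survival
#' trajectory to smolt size: allometric growth constant `alpha`, emergence
#' mass `M_1`, smolt threshold, and the size-dependent mortality rate
#' `mu = X_u * M^f`. `T_corr` shifts the laboratory-fitted curve 3 degrees C
#' cooler to represent field conditions; `Food` scales growth for ration
#' limitation (0.65 reflects field feeding relative to ad libitum).
#'
#' @param d,g shape parameters of the growth curve.
#' @param T_L,T_U lower/upper thermal limits of (uncorrected) growth,
#'   degrees C.
#' @param T_corr field temperature correction, degrees C.
#' @param Food feeding level in (0, 1]; 1 = ad libitum.
#' @param alpha allometric growth constant.
#' @param M_1 fry emergence mass, g.
#' @param smolt_mass smolting size threshold, g.
#' @param X_u background mortality rate per day for a 1 g fish.
#' @param f allometric mortality scaling exponent.
#' @param max_days cap on the trajectory length, days.
#' @return A `growth_params` object.
#' @export
growth_params <- function(d = 0.415, g = 0.315,
                          T_L = 1.833, T_U = 24.918,
                          T_corr = 3.0, Food = 0.65,
                          alpha = 0.338, M_1 = 0.46, smolt_mass = 6,
                          X_u = 0.00753, f = -0.27,
                          max_days = 365L) {
  if (T_L >= T_U) abort("`T_L` must be below `T_U`.")
  if (Food <= 0 || Food > 1) abort("`Food` must lie in (0, 1].")
  if (!(smolt_mass > M_1 && M_1 > 0)) abort("Need smolt_mass > M_1 > 0.")
  assert_scalar_number(alpha, "alpha", positive = TRUE)
  assert_scalar_number(X_u, "X_u", positive = TRUE)
  structure(
    list(
      d = d, g = g, T_L = T_L, T_U = T_U, T_corr = T_corr, Food = Food,
      alpha = alpha, M_1 = M_1, smolt_mass = smolt_mass,
      X_u = X_u, f = f, max_days = as.integer(max_days)
    ),
    class = "growth_params"
  )
}

#' Adult energy-budget parameters
#'
#' The spawning-success energy ledger: a female enters freshwater with muscle
#' energy density `E_I ~ Normal(E_I_mean, E_I_sd)` (MJ/kg), pays a fixed
#' migration cost `E_M`, allocates `gonad_fraction` of her starting energy to
#' gonads, and pays the temperature-dependent holding cost; she spawns
#' successfully if the remainder stays at or above the post-spawn carcass
#' floor `E_D`. Presets follow the two Central Valley run types: spring-run
#' (11.7 +/- 1.0 MJ/kg, migration 2.5) and fall-run (8.0 +/- 1.0, migration
#' 2.0); both invest 14% of starting energy in gonads and share `E_D = 3.4`.
#'
#' @param run `"spring"` or `"fall"` preset.
#' @param E_I_mean,E_I_sd initial muscle energy density, MJ/kg.
#' @param E_M migration cost, MJ/kg.
#' @param gonad_fraction fraction of the drawn `E_I` allocated to gonads.
#' @param E_D post-spawn energy floor, MJ/kg.
#' @param n_draws Monte Carlo draws per pixel.
#' @return An `energy_budget_params` object.
#' @export
energy_budget_params <- function(run = c("spring", "fall"),
                                 E_I_mean = NULL, E_I_sd = 1.0,
                                 E_M = NULL, gonad_fraction = 0.14,
                                 E_D = 3.4, n_draws = 1000L) {
  run <- match.arg(run)
  E_I_mean <- E_I_mean %||% switch(run, spring = 11.7, fall = 8.0)
  E_M <- E_M %||% switch(run, spring = 2.5, fall = 2.0)
  assert_scalar_number(E_I_sd, "E_I_sd", positive = TRUE)
  if (gonad_fraction <= 0 || gonad_fraction >= 1) {
    abort("`gonad_fraction` must lie in (0, 1).")
  }
  if (E_I_mean <= E_M + E_D) {
    abort("`E_I_mean` must exceed E_M + E_D for a viable budget.")
  }
  if (n_draws < 1) abort("`n_draws` must be a positive integer.")
  structure(
    list(
      run = run, E_I_mean = E_I_mean, E_I_sd = E_I_sd, E_M = E_M,
      gonad_fraction = gonad_fraction, E_D = E_D, n_draws = as.integer(n_draws)
    ),
    class = "energy_budget_params"
  )
}

#' @export
print.holding_params <- function(x, ...) {
  cat("<holding_params> B_h = c0 * M^b * exp(D*T)\n")
  cat(sprintf("  c0 = %.2f mgO2/d/kg, b = %.3f, D = %.3f /degC, M = %.2f kg\n",
              x$c0, x$b, x$D, x$M_adult))
  invisible(x)
}

#' @export
print.embryo_params <- function(x, ...) {
  cat(sprintf("<embryo_params> s_T = %.3f, T_crit = %.1f degC, dev = %.6f*T + %.5f\n",
              x$s_T, x$T_crit, x$dev_slope, x$dev_intercept))
  invisible(x)
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf(
    "<growth_params> d = %.3f, g = %.3f, T_L = %.3f, T_U = %.3f, T_corr = %.1f, Food = %.2f\n",
    x$d, x$g, x$T_L, x$T_U, x$T_corr, x$Food))
  cat(sprintf("  alpha = %.3f, M_1 = %.2f g -> smolt %.1f g; mu = %.5f * M^%.2f\n",
              x$alpha, x$M_1, x$smolt_mass, x$X_u, x$f))
  invisible(x)
}

#' @export
print.energy_budget_params <- function(x, ...) {
  cat(sprintf(
    "<energy_budget_params> %s-run: E_I = %.1f +/- %.1f, E_M = %.1f, gonads %.0f%%, E_D = %.1f MJ/kg (%d draws)\n",
    x$run, x$E_I_mean, x$E_I_sd, x$E_M, 100 * x$gonad_fraction, x$E_D, x$n_draws))
  invisible(x)
}

# one row per parameter, shared by the param tidiers
params_tidy <- function(x) {
  flat <- purrr::keep(unclass(x), is.numeric)
  tibble::tibble(term = names(flat), value = unlist(flat, use.names = FALSE))
}

#' Tidy a parameter bundle
#'
#' @param x a `holding_params`, `embryo_params`, `growth_params` or
#'   `energy_budget_params` object.
#' @param ... unused.
#' @return A tibble with columns `term`, `value`.
#' @export
tidy.holding_params <- function(x, ...) params_tidy(x)

#' @rdname tidy.holding_params
#' @export
tidy.embryo_params <- function(x, ...) params_tidy(x)

#' @rdname tidy.holding_params
#' @export
tidy.growth_params <- function(x, ...) params_tidy(x)

#' @rdname tidy.holding_params
#' @export
tidy.energy_budget_params <- function(x, ...) params_tidy(x)
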