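# map Julian-day draws to grid columns; first column at or after `from_col`
# whose calendar day matches. Returns NA when the grid ends first.
make_day_col_lookup <- function(dates) {
  ydays <- jday(dates)
  cols_by_day <- split(seq_along(dates), ydays)
  function(day, from_col = 1L) {
    key <- as.character(day)
    cols <- cols_by_day[[key]]
    if (is.null(cols)) return(NA_integer_)
    hit <- cols[cols >= from_col]
    if (length(hit) == 0L) NA_integer_ else hit[1]
  }
}

#' Likelihood-of-spawning surface for holding adults
#'
#' Each pixel `(km, date)` is read as an adult arriving at that km on that
#' date. Per pixel, `n_draws` Monte Carlo replicates draw a spawn date from
#' the (Gaussian) spawn phenology truncated to on-or-after arrival, and an
#' initial energy density from the run's budget; the holding cost is the
#' summed daily metabolic expenditure at the pixel's km between arrival and
#' spawning. A replicate succeeds when
#' `E_I - E_M - gonad_fraction * E_I - E_H >= E_D`; the pixel value is the
#' percent of successful replicates. Adults arriving after peak spawning (the
#' phenology mean) spawn immediately with no holding cost. Pixels outside the
#' arrival-to-spawn season (earliest arrival minus `buffer_days` to last
#' spawn plus `buffer_days`, taken at the 0.5%/99.5% phenology quantiles) or
#' whose holding path crosses missing temperature data are masked.
#'
#' Randomness is fully reproducible: each pixel uses a deterministic
#' substream derived from `seed`, so results are independent of pixel
#' evaluation order.
#'
#' @param grid a [temp_grid()].
#' @param spawn_phenology a [gaussian_dist()] over spawn Julian day.
#' @param budget an [energy_budget_params()] bundle.
#' @param hold_params a [holding_params()] bundle.
#' @param arrival_phenology optional [gaussian_dist()] over arrival Julian
#'   day, used for the early edge of the season window; defaults to the
#'   spawn phenology.
#' @param buffer_days days added on both ends of the season window so early
#'   arrivals and late spawners are still scored.
#' @param seed integer seed (required; reproducibility contract).
#' @return A `survival_surface` (stage `"spawning"`).
#' @export
spawning_success_surface <- function(grid, spawn_phenology, budget,
                                     hold_params = holding_params(),
                                     arrival_phenology = NULL,
                                     buffer_days = 30L, seed) {
  stopifnot(inherits(grid, "temp_grid"), inherits(budget, "energy_budget_params"))
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is required: spawning surfaces are Monte Carlo estimates.")
  }
  check_gaussian_dist(spawn_phenology, "day")
  arr <- arrival_phenology %||% spawn_phenology
  check_gaussian_dist(arr, "day")

  n_km <- length(grid$kms)
  n_day <- length(grid$dates)
  ydays <- jday(grid$dates)
  day_col <- make_day_col_lookup(grid$dates)

  window_lo <- floor(qnorm(0.005, arr$mean, arr$sd)) - buffer_days
  window_hi <- ceiling(qnorm(0.995, spawn_phenology$mean, spawn_phenology$sd)) + buffer_days
  in_window <- ydays >= window_lo & ydays <= window_hi

  vals <- matrix(NA_real_, n_km, n_day)
  mask <- matrix(FALSE, n_km, n_day)
  gf <- budget$gonad_fraction

  for (ki in seq_len(n_km)) {
    temps_k <- ifelse(grid$mask[ki, ], grid$values[ki, ], NA_real_)
    # daily holding cost (MJ/kg); NA poisons cumulative sums so any path
    # through a data hole yields a non-finite E_H and the pixel is masked
    cost <- ifelse(is.na(temps_k), NA_real_,
                   holding_metabolic_rate(ifelse(is.na(temps_k), 0, temps_k), hold_params) *
                     hold_params$t_step * hold_params$oxycal)
    ccost <- c(0, cumsum(ifelse(is.na(cost), Inf, cost)))
    for (ci in seq_len(n_day)) {
      if (!in_window[ci]) next
      a_day <- ydays[ci]
      px_seed <- derive_seed(seed, ki, ci)
      res <- with_seed(px_seed, {
        if (a_day > spawn_phenology$mean) {
          # late arrival: spawn immediately, no holding cost
          e_h <- rep(0, budget$n_draws)
          ok_path <- grid$mask[ki, ci]
        } else {
          p_lo <- pnorm(a_day, spawn_phenology$mean, spawn_phenology$sd)
          if (p_lo >= 1 - 1e-12) {
            e_h <- rep(0, budget$n_draws)
            ok_path <- grid$mask[ki, ci]
          } else {
            u <- runif(budget$n_draws, p_lo, 1)
            s_day <- pmax(round(qnorm(u, spawn_phenology$mean, spawn_phenology$sd)), a_day)
            s_uniq <- sort(unique(s_day))
            s_col <- vapply(s_uniq, day_col, integer(1), from_col = ci)
            cols <- s_col[match(s_day, s_uniq)]
            if (anyNA(cols)) {
              e_h <- NA_real_
              ok_path <- FALSE
            } else {
              e_h <- ccost[cols] - ccost[ci]
              ok_path <- all(is.finite(e_h))
            }
          }
        }
        if (!isTRUE(ok_path)) {
          NA_real_
        } else {
          e_i <- rnorm(budget$n_draws, budget$E_I_mean, budget$E_I_sd)
          100 * mean(e_i * (1 - gf) - budget$E_M - e_h >= budget$E_D)
        }
      })
      if (!is.na(res)) {
        vals[ki, ci] <- res
        mask[ki, ci] <- TRUE
      }
    }
  }
  new_survival_surface(grid, vals, mask, stage = "spawning",
                       population = budget$run)
}

#' Egg-to-fry survival surface
#'
#' Each pixel `(km, date)` is read as a redd spawned at that km on that
#' date. The incubation duration is the maturation sum evaluated on the
#' forward temperature path; the pixel value is
#' `100 * (1 - M_T)`, the percent egg-to-fry survival over that incubation
#' period. Pixels whose path ends (or hits missing data, or the incubation
#' cap) before emergence are masked.
#'
#' @param grid a [temp_grid()].
#' @param p an [embryo_params()] bundle.
#' @return A `survival_surface` (stage `"egg_to_fry"`).
#' @export
egg_to_fry_surface <- function(grid, p = embryo_params()) {
  stopifnot(inherits(grid, "temp_grid"), inherits(p, "embryo_params"))
  n_km <- length(grid$kms)
  n_day <- length(grid$dates)
  vals <- matrix(NA_real_, n_km, n_day)
  mask <- matrix(FALSE, n_km, n_day)
  for (ki in seq_len(n_km)) {
    temps_k <- ifelse(grid$mask[ki, ], grid$values[ki, ], NA_real_)
    inc <- p$dev_slope * temps_k + p$dev_intercept
    # next_na[s]: first missing day at or after s (n_day + 1 when none)
    na_flag <- ifelse(is.na(inc), seq_len(n_day), n_day + 1L)
    next_na <- rev(cummin(rev(na_flag)))
    cdev <- c(0, cumsum(ifelse(is.na(inc), 0, inc)))
    cex <- c(0, cumsum(ifelse(is.na(temps_k), 0, pmax(0, temps_k - p$T_crit))))
    for (s in seq_len(n_day)) {
      target <- cdev[s] + 1
      m <- findInterval(target - 1e-12, cdev)  # absolute index of emergence day
      if (m > n_day || m >= next_na[s]) next
      n_inc <- m - s + 1L
      if (n_inc > p$max_incubation_days) next
      surv <- exp(-p$s_T * (cex[m + 1L] - cex[s]))
      vals[ki, s] <- 100 * surv
      mask[ki, s] <- TRUE
    }
  }
  new_survival_surface(grid, vals, mask, stage = "egg_to_fry")
}

#' Daily mass and survival trajectory of a rearing juvenile
#'
#' Iterates the daily growth update
#' `M_{t+1} = M_t + (Omega(T_t)/100) * M_t^(1-alpha)` from emergence mass
#' `M_1` along a temperature path, accumulating survival
#' `S_{t+1} = S_t * exp(-mu)` with the size-dependent mortality rate
#' `mu = X_u * M^f`. By default `mu` uses the start-of-day mass
#' (`mortality_mass = "pre"`); `"post"` evaluates it at the day's updated
#' mass. Mortality applies on every day up to and including the day smolt
#' size is reached.
#'
#' Day counting follows the emergence-day-one convention: the fry is at mass
#' `M_1` on day 1, so a fish whose 82nd update crosses the threshold is at
#' smolt size on day 83.
#'
#' @param temps temperature path from emergence day onwards, degrees C.
#' @param p a [growth_params()] bundle.
#' @param mortality_mass which mass enters the daily mortality rate.
#' @return A tibble with one row per daily update: `day` (the start-of-day
#'   index, emergence = day 1), `temp_c`, `mass_start`, `mass_end`,
#'   `survival` (cumulative, end of day), `smolted`.
#' @export
smolt_trajectory <- function(temps, p = growth_params(),
                             mortality_mass = c("pre", "post")) {
  stopifnot(inherits(p, "growth_params"))
  mortality_mass <- match.arg(mortality_mass)
  n <- min(length(temps), p$max_days)
  day <- integer(0); m0 <- numeric(0); m1 <- numeric(0); sv <- numeric(0); tc <- numeric(0)
  mass <- p$M_1
  surv <- 1
  for (t in seq_len(n)) {
    Tt <- temps[t]
    if (!is.finite(Tt)) break
    omega <- juvenile_growth_rate(Tt, p)
    new_mass <- mass + (omega / 100) * mass^(1 - p$alpha)
    if (new_mass <= 0) break
    mu <- p$X_u * (if (mortality_mass == "pre") mass else new_mass)^p$f
    surv <- surv * exp(-mu)
    day <- c(day, t); tc <- c(tc, Tt); m0 <- c(m0, mass); m1 <- c(m1, new_mass); sv <- c(sv, surv)
    mass <- new_mass
    if (mass >= p$smolt_mass) break
  }
  tibble::tibble(
    day = day, temp_c = tc, mass_start = m0, mass_end = m1,
    survival = sv, smolted = m1 >= p$smolt_mass
  )
}

#' Maximum smolting survival at the thermal optimum
#'
#' Runs the daily trajectory at the constant field temperature maximizing
#' growth and returns the terminal survival and day count — the benchmark
#' against which per-pixel smolting success is expressed.
#'
#' @param p a [growth_params()] bundle.
#' @param mortality_mass passed to [smolt_trajectory()].
#' @return A list with `survival` (probability) and `days` (the day index on
#'   which the fish is at smolt size, counting emergence as day 1).
#' @export
max_smolt_survival <- function(p = growth_params(),
                               mortality_mass = c("pre", "post")) {
  mortality_mass <- match.arg(mortality_mass)
  t_opt <- optimal_growth_temperature(p)
  traj <- smolt_trajectory(rep(t_opt, p$max_days), p, mortality_mass)
  if (nrow(traj) == 0L || !any(traj$smolted)) {
    abort("Smolt size not attainable at the growth optimum; check parameters.")
  }
  last <- traj[nrow(traj), ]
  list(survival = last$survival, days = as.integer(last$day) + 1L)
}

#' Smolting success surface
#'
#' Each pixel `(km, date)` is read as a fry emerging at that km on that
#' date. The juvenile grows along the forward temperature path until it
#' reaches smolt size; the pixel value is its survival to that day as a
#' percent of the optimum-temperature maximum ([max_smolt_survival()]).
#' Pixels whose path ends or hits missing data before smolt size are masked;
#' pixels where smolt size is never attained despite complete data (growth
#' too slow within the cap) are masked by default, or scored 0 with
#' `non_attainment = "zero"`.
#'
#' @param grid a [temp_grid()].
#' @param p a [growth_params()] bundle.
#' @param non_attainment `"mask"` or `"zero"`.
#' @param mortality_mass passed to [smolt_trajectory()].
#' @return A `survival_surface` (stage `"smolting"`).
#' @export
smolting_success_surface <- function(grid, p = growth_params(),
                                     non_attainment = c("mask", "zero"),
                                     mortality_mass = c("pre", "post")) {
  stopifnot(inherits(grid, "temp_grid"), inherits(p, "growth_params"))
  non_attainment <- match.arg(non_attainment)
  mortality_mass <- match.arg(mortality_mass)
  s_max <- max_smolt_survival(p, mortality_mass)$survival
  n_km <- length(grid$kms)
  n_day <- length(grid$dates)
  vals <- matrix(NA_real_, n_km, n_day)
  mask <- matrix(FALSE, n_km, n_day)
  for (ki in seq_len(n_km)) {
    temps_k <- ifelse(grid$mask[ki, ], grid$values[ki, ], NA_real_)
    # vectorized across emergence days: every start column advances one day
    # per iteration through its own offset window
    mass <- rep(p$M_1, n_day)
    surv <- rep(1, n_day)
    state <- rep(0L, n_day) # 0 growing, 1 smolted, -1 data ran out, -2 cap/no growth
    for (t in 0:(p$max_days - 1L)) {
      act <- which(state == 0L)
      if (length(act) == 0L) break
      idx <- act + t
      off_grid <- idx > n_day
      state[act[off_grid]] <- -1L
      act <- act[!off_grid]
      idx <- idx[!off_grid]
      if (length(act) == 0L) next
      Tt <- temps_k[idx]
      bad <- is.na(Tt)
      state[act[bad]] <- -1L
      act <- act[!bad]
      Tt <- Tt[!bad]
      if (length(act) == 0L) next
      omega <- juvenile_growth_rate(Tt, p)
      m_old <- mass[act]
      m_new <- m_old + (omega / 100) * m_old^(1 - p$alpha)
      dead <- m_new <= 0
      state[act[dead]] <- -2L
      keep <- !dead
      act <- act[keep]
      if (length(act) == 0L) next
      m_old <- m_old[keep]
      m_new <- m_new[keep]
      mu <- p$X_u * (if (mortality_mass == "pre") m_old else m_new)^p$f
      surv[act] <- surv[act] * exp(-mu)
      mass[act] <- m_new
      state[act[m_new >= p$smolt_mass]] <- 1L
    }
    state[state == 0L] <- -2L # cap hit while still growing
    done <- state == 1L
    vals[ki, done] <- 100 * surv[done] / s_max
    mask[ki, done] <- TRUE
    if (non_attainment == "zero") {
      z <- state == -2L
      vals[ki, z] <- 0
      mask[ki, z] <- TRUE
    }
  }
  vals[mask] <- pmin(vals[mask], 100)
  new_survival_surface(grid, vals, mask, stage = "smolting")
}

#' Longest affordable holding duration at constant temperature
#'
#' For an average-energy female of the given budget, finds the largest whole
#' number of holding days at constant temperature `T` after which the energy
#' remaining (`E_I - E_M - gonad_fraction * E_I - n * daily_cost`) still
#' meets the post-spawn floor `E_D`.
#'
#' @param T constant holding temperature, degrees C.
#' @param budget an [energy_budget_params()] bundle.
#' @param hold_params a [holding_params()] bundle.
#' @return Largest affordable holding duration, whole days.
#' @export
max_holding_days <- function(T, budget = energy_budget_params("spring"),
                             hold_params = holding_params()) {
  stopifnot(inherits(budget, "energy_budget_params"))
  daily <- holding_energy_total(T, hold_params)
  spare <- budget$E_I_mean * (1 - budget$gonad_fraction) - budget$E_M - budget$E_D
  as.integer(floor(spare / daily))
}
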