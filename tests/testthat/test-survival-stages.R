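test_that("the spawning energy ledger behaves as a scalar budget", {
  b <- energy_budget_params("spring")
  hp <- holding_params()
  # mean-energy fish arriving at the peak (no holding): 11.7 - 2.5 - 1.638 = 7.562 >= 3.4
  remaining <- b$E_I_mean - b$E_M - b$gonad_fraction * b$E_I_mean - 0
  expect_equal(remaining, 7.562)
  expect_gte(remaining, b$E_D)

  # at constant 16 C the mean-energy spring fish affords 101 whole holding days
  expect_equal(max_holding_days(16, b, hp), 101L)
  daily <- holding_energy_total(16, hp)
  expect_gte(b$E_I_mean * (1 - b$gonad_fraction) - b$E_M - 101 * daily, b$E_D)
  expect_lt(b$E_I_mean * (1 - b$gonad_fraction) - b$E_M - 110 * daily, b$E_D)

  expect_error(energy_budget_params("spring", E_I_mean = 5), "viable")
})

test_that("degenerate energy and spawn-date distributions give an all-or-nothing surface", {
  grid <- flat_grid(16, n_km = 2, n_days = 160, start = "2013-06-01")
  # spawn phenology pinned (tiny sd) on Julian day 260; near-deterministic energy
  sp <- gaussian_dist(260, 1e-6, "day")
  b_rich <- energy_budget_params("spring", E_I_sd = 1e-9, n_draws = 200)
  s <- spawning_success_surface(grid, sp, b_rich, seed = 1, buffer_days = 10,
                                arrival_phenology = gaussian_dist(200, 25, "day"))
  vals <- valid_values(s)
  expect_true(all(vals %in% c(0, 100)))
  # arrivals at/after the peak spawn immediately -> always successful
  peak_col <- match(260L, jday(s$dates))
  expect_equal(s$values[1, peak_col], 100)
  # long-holding pixels (early arrival) run out of energy -> 0 present too
  expect_true(any(vals == 0))
  # non-increasing in holding duration at constant temperature
  row1 <- s$values[1, s$mask[1, ]]
  expect_true(all(diff(row1) >= 0)) # later arrival = shorter holding = better
})

test_that("Monte Carlo spawning success matches the quadrature oracle at a fixed pixel", {
  grid <- flat_grid(16.5, n_km = 1, n_days = 140, start = "2013-06-10")
  sp <- gaussian_dist(250, 8, "day")
  b <- energy_budget_params("spring", n_draws = 1000)
  surf <- spawning_success_surface(grid, sp, b, seed = 77, buffer_days = 15)

  # independent oracle: discretize the truncated spawn-date law by day cell,
  # then integrate the Gaussian energy tail in closed form
  oracle_pct <- function(a_day, temp) {
    daily <- holding_energy_total(temp, holding_params())
    if (a_day > sp$mean) {
      days <- a_day
      w <- 1
    } else {
      # truncated at arrival, rounded to days, rounded-down draws clamp to a
      days <- a_day:366
      lo <- pnorm(a_day, sp$mean, sp$sd)
      hi_cdf <- pnorm(days + 0.5, sp$mean, sp$sd)
      lo_cdf <- pnorm(days - 0.5, sp$mean, sp$sd)
      w <- (hi_cdf - lo_cdf) / (1 - lo)
      w[1] <- (hi_cdf[1] - lo) / (1 - lo)
      w <- pmax(w, 0)
    }
    e_h <- (days - a_day) * daily
    thr <- (b$E_M + e_h + b$E_D) / (1 - b$gonad_fraction)
    100 * sum(w * (1 - pnorm(thr, b$E_I_mean, b$E_I_sd)))
  }
  cols <- which(surf$mask[1, ])
  probe <- cols[round(seq(1, length(cols), length.out = 5))]
  for (ci in probe) {
    a_day <- jday(surf$dates)[ci]
    expect_lt(abs(surf$values[1, ci] - oracle_pct(a_day, 16.5)), 3)
  }
})

test_that("spawning surfaces are seeded, reproducible, and demand a seed", {
  grid <- flat_grid(15, n_km = 2, n_days = 120, start = "2013-07-01")
  sp <- gaussian_dist(260, 6, "day")
  # a marginal budget keeps success strictly between 0 and 100, so the
  # Monte Carlo noise (and hence the seed) is visible in the values
  b <- energy_budget_params("spring", E_I_mean = 7.3, n_draws = 300)
  s1 <- spawning_success_surface(grid, sp, b, seed = 5, buffer_days = 10)
  s2 <- spawning_success_surface(grid, sp, b, seed = 5, buffer_days = 10)
  expect_identical(s1$values, s2$values)
  s3 <- spawning_success_surface(grid, sp, b, seed = 6, buffer_days = 10)
  expect_false(identical(s1$values, s3$values))
  expect_error(spawning_success_surface(grid, sp, b, buffer_days = 10), "seed")
})

test_that("warmer holding paths never raise spawning success (fixed draws)", {
  sp <- gaussian_dist(255, 5, "day")
  b <- energy_budget_params("spring", n_draws = 500)
  cool <- spawning_success_surface(flat_grid(14, 1, 130, "2013-06-15"), sp, b,
                                   seed = 9, buffer_days = 10)
  warm <- spawning_success_surface(flat_grid(17, 1, 130, "2013-06-15"), sp, b,
                                   seed = 9, buffer_days = 10)
  both <- cool$mask[1, ] & warm$mask[1, ]
  expect_true(all(warm$values[1, both] <= cool$values[1, both] + 1e-9))
})

test_that("egg-to-fry surface follows the closed forms and masks incomplete paths", {
  # below T_crit everywhere: survival is exactly 100%
  cold <- egg_to_fry_surface(flat_grid(10, 1, 200, "2013-10-01"))
  expect_true(all(valid_values(cold) == 100))
  # constant 13 C: 71-day incubation, survival = exp(-0.024*71) ~ 18.2%
  warm13 <- egg_to_fry_surface(flat_grid(13, 1, 200, "2013-10-01"))
  expect_equal(warm13$values[1, 1], 100 * exp(-0.024 * 71), tolerance = 1e-9)
  # last pixels lack a complete forward path and are masked
  expect_false(warm13$mask[1, 200])
  expect_equal(sum(warm13$mask[1, ]), 200 - 71 + 1)
  # warmer: shorter incubation but strictly lower survival above T_crit
  warm15 <- egg_to_fry_surface(flat_grid(15, 1, 200, "2013-10-01"))
  n13 <- ceiling(1 / (0.001044 * 13 + 0.00056))
  n15 <- ceiling(1 / (0.001044 * 15 + 0.00056))
  expect_lt(n15, n13)
  expect_lt(warm15$values[1, 1], warm13$values[1, 1])
  expect_equal(warm15$values[1, 1], 100 * exp(-0.024 * 3 * n15), tolerance = 1e-9)
})

test_that("egg-to-fry survival never increases when any single day warms above T_crit", {
  g <- flat_grid(12.5, 1, 150, "2013-10-01")
  g_b <- g
  g_b$values[1, 20] <- g_b$values[1, 20] + 2 # one warmer day inside incubation
  s_a <- egg_to_fry_surface(g)
  s_b <- egg_to_fry_surface(g_b)
  both <- s_a$mask[1, ] & s_b$mask[1, ]
  expect_true(all(s_b$values[1, both] <= s_a$values[1, both] + 1e-12))
})

test_that("smolt trajectory hits the analytic benchmark at the optimum", {
  p <- growth_params()
  mx <- max_smolt_survival(p)
  expect_equal(mx$days, 83L)
  expect_equal(mx$survival, 0.5922696, tolerance = 1e-6)

  # continuous-time oracle: t = (smolt^a - M1^a) / (a * Omega_max/100)
  t_opt <- optimal_growth_temperature(p, tol = 1e-6)
  om <- juvenile_growth_rate(t_opt, p)
  t_cont <- (p$smolt_mass^p$alpha - p$M_1^p$alpha) / (p$alpha * om / 100)
  expect_lt(abs(mx$days - t_cont) / t_cont, 0.05)

  # ad libitum food: strictly faster and better-surviving than Food = 0.65
  mx1 <- max_smolt_survival(growth_params(Food = 1))
  expect_lt(mx1$days, mx$days)
  expect_gt(mx1$survival, mx$survival)

  # both mass-update conventions are available and nearly coincide
  mx_post <- max_smolt_survival(p, mortality_mass = "post")
  expect_equal(mx_post$survival, 0.5950388, tolerance = 1e-6)
  expect_equal(mx_post$days, mx$days)
})

test_that("smolting surface self-normalizes and handles non-attainment", {
  p <- growth_params()
  t_opt <- optimal_growth_temperature(p)
  # constant optimal temperature: every complete pixel scores 100%
  s_opt <- smolting_success_surface(flat_grid(t_opt, 1, 200, "2013-03-01"), p)
  expect_true(all(abs(valid_values(s_opt) - 100) < 1e-9))
  # the surface agrees with the scalar trajectory at a cooler temperature
  s_cool <- smolting_success_surface(flat_grid(10, 1, 365, "2013-01-01"), p)
  tr <- smolt_trajectory(rep(10, 365), p)
  expect_equal(s_cool$values[1, 1],
               100 * tr$survival[nrow(tr)] / max_smolt_survival(p)$survival,
               tolerance = 1e-9)
  # growth non-positive throughout: never smolts; masked by default, 0 on demand
  s_hot <- smolting_success_surface(flat_grid(23, 1, 365, "2013-01-01"), p)
  expect_equal(sum(s_hot$mask), 0)
  s_hot0 <- smolting_success_surface(flat_grid(23, 1, 365, "2013-01-01"), p,
                                     non_attainment = "zero")
  expect_true(all(valid_values(s_hot0) == 0))
  # pixels whose forward path leaves the grid stay masked either way
  s_short <- smolting_success_surface(flat_grid(t_opt, 1, 40, "2013-03-01"), p)
  expect_equal(sum(s_short$mask), 0) # 40-day grid can never finish an 83-day rearing
})
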