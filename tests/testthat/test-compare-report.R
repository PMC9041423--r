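test_that("comparison summaries compute the mitigation index identities", {
  # identical vectors -> index 0
  s0 <- summarize_comparison(rep(40, 50), rep(40, 50))
  expect_equal(mitigation_index(s0), 0)
  expect_equal(s0$weighting, c("weighted", "unweighted"))
  expect_equal(s0$mean, c(40, 40))

  # all-100 weighted against an unweighted mean of 40 -> index 60
  s1 <- summarize_comparison(rep(100, 30), c(rep(0, 30), rep(80, 30)))
  expect_equal(mitigation_index(s1), 60)
  expect_true(all(s1$p05 <= s1$q25 & s1$q25 <= s1$median &
                    s1$median <= s1$q75 & s1$q75 <= s1$p95))

  expect_error(summarize_comparison(numeric(0), rep(1, 3)), "empty")
})

test_that("heatmap tables round-trip with a sentinel for masked cells", {
  g <- flat_grid(13, n_km = 3, n_days = 4, start = "2013-01-01")
  g$values[2, 3] <- NA
  g$mask[2, 3] <- FALSE
  path <- withr::local_tempfile(fileext = ".csv")
  export_heatmap_table(g, path)
  lines <- readLines(path)
  expect_equal(length(lines), 1 + 1 + 3) # comment header + column row + 3 km rows
  # masked cell is the NA sentinel in the file, never 0
  expect_match(lines[4], "NA")
  back <- read_heatmap_table(path)
  expect_equal(back$values[!is.na(back$values)], g$values[g$mask])
  expect_equal(back$mask, g$mask)
  expect_equal(back$dates, g$dates)

  # survival surfaces keep stage/population metadata through the round trip
  surf <- egg_to_fry_surface(flat_grid(11, 2, 120, "2013-10-01"))
  path2 <- withr::local_tempfile(fileext = ".csv")
  export_heatmap_table(surf, path2)
  back2 <- read_heatmap_table(path2)
  expect_s3_class(back2, "survival_surface")
  expect_equal(back2$stage, "egg_to_fry")
  expect_equal(back2$values[back2$mask], surf$values[surf$mask])
})

test_that("config validation rejects malformed runs before any computation", {
  cfg <- demo_config()
  expect_s3_class(read_config(cfg), "thermal_config")
  bad <- cfg
  bad$unknown_key <- 1
  expect_error(read_config(bad), "Unknown config key")
  bad2 <- cfg
  bad2$stages <- c("spawning", "adulthood")
  expect_error(read_config(bad2), "Unknown stage")
  bad3 <- cfg
  bad3$seed <- NULL
  expect_error(read_config(bad3), "seed")
  bad4 <- cfg
  bad4$populations[[1]]$name <- NULL
  expect_error(read_config(bad4), "unique `name`")
})

test_that("the full pipeline runs a synthetic scenario and is deterministic", {
  cfg <- demo_config(seed = 42)
  run1 <- run_pipeline(cfg)
  # all three stage summaries exist with values inside [0, 100]
  expect_setequal(unique(run1$summary$stage), c("spawning", "egg_to_fry", "smolting"))
  expect_true(all(run1$summary$mean >= 0 & run1$summary$mean <= 100))
  for (surf in run1$populations$spring_run$surfaces) {
    v <- valid_values(surf)
    expect_true(all(v >= 0 & v <= 100))
  }
  # a rerun with the same config and seed is identical, including on disk
  run2 <- run_pipeline(cfg)
  expect_identical(tidy(run1), tidy(run2))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_run(run1, d1)
  write_run(run2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed changes the Monte Carlo surfaces
  run3 <- run_pipeline(demo_config(seed = 43))
  expect_false(identical(tidy(run1), tidy(run3)))
  # broom-style accessors
  expect_s3_class(tidy(run1), "tbl_df")
  expect_equal(glance(run1)$n_populations, 1)
})

test_that("pipelines can be configured from YAML files and fitted count tables", {
  cfg <- demo_config(seed = 7)
  # phenology via synthetic count tables instead of direct parameters
  cfg$populations[[1]]$arrival <- list(
    counts = generate_count_table(150, 12, 2000, n_years = 2, seed = 1)
  )
  path <- withr::local_tempfile(fileext = ".yaml")
  cfg_yaml <- cfg
  cfg_yaml$populations[[1]]$arrival <- list(mean = 150, sd = 12)
  yaml::write_yaml(cfg_yaml, path)
  run_file <- run_pipeline(path)
  run_list <- run_pipeline(cfg)
  # the fitted arrival distribution is close to the directly specified one
  fitted <- run_list$populations$spring_run$dists$arrival
  expect_lt(abs(fitted$mean - 150), 1.5)
  expect_lt(abs(fitted$sd - 12), 1.5)
  expect_s3_class(run_file, "thermal_run")
})

test_that("reintroduction mode applies donor timing with host spatial habits", {
  cfg <- demo_config(seed = 5)
  cfg$stages <- c("egg_to_fry")
  fall <- list(
    name = "fall_run", run = "fall",
    arrival = list(mean = 280, sd = 10),
    spawn = list(mean = 320, sd = 8),
    emergence = list(mean = 50, sd = 10),
    redds = list(mean = 4, sd = 2),
    rearing = list(mean = 4, sd = 2)
  )
  hypo <- fall
  hypo$name <- "hypothetical_spring"
  hypo$phenology_from <- "spring_run"
  cfg$populations <- c(cfg$populations, list(fall), list(hypo))
  run <- run_pipeline(cfg)
  d <- run$populations$hypothetical_spring$dists
  # timing comes from the donor, spatial distributions stay the host's
  expect_equal(d$spawning$mean, 265)
  expect_equal(d$redds$mean, 4)
  bad <- cfg
  bad$populations[[3]]$phenology_from <- "nobody"
  expect_error(run_pipeline(bad), "unknown population")
})

test_that("donor spring timing on a hotter river lowers spawning and egg survival", {
  # a cool river supporting a spring run, and a warmer river where the same
  # timing is applied hypothetically (reintroduction scenario)
  spring <- list(
    name = "spring_run", run = "spring",
    arrival = list(mean = 150, sd = 12),
    spawn = list(mean = 265, sd = 10),
    emergence = list(mean = 20, sd = 10),
    redds = list(mean = 8, sd = 2),
    rearing = list(mean = 6, sd = 2)
  )
  base <- list(
    seed = 11,
    river = list(length_km = 10, start = "2013-01-01", end = "2014-06-30",
                 mean_annual_temp = 12, seasonal_amplitude = 7, peak_day = 205,
                 downstream_warming = 0.1, daily_noise_sd = 0),
    populations = list(spring),
    stages = c("spawning", "egg_to_fry")
  )
  hot <- base
  hot$river$mean_annual_temp <- 16
  run_cool <- run_pipeline(base)
  run_hot <- run_pipeline(hot)
  for (stg in c("spawning", "egg_to_fry")) {
    m_cool <- run_cool$summary$mean[run_cool$summary$stage == stg &
                                      run_cool$summary$weighting == "weighted"]
    m_hot <- run_hot$summary$mean[run_hot$summary$stage == stg &
                                    run_hot$summary$weighting == "weighted"]
    expect_lt(m_hot, m_cool)
  }
})

test_that("plot methods return ggplot objects without evaluation errors", {
  g <- generate_true_field(demo_river(4))
  expect_s3_class(autoplot(g), "ggplot")
  surf <- egg_to_fry_surface(g)
  expect_s3_class(autoplot(surf), "ggplot")
  df <- tibble::tibble(
    stage = rep(c("spawning", "egg_to_fry"), each = 20),
    population = "demo",
    weighting = rep(c("weighted", "unweighted"), 20),
    likelihood_pct = runif(40, 0, 100)
  )
  p <- plot_comparison(df)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gt(length(built$data), 0)
})
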