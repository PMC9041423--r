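#' Summarize weighted vs unweighted survival for a life stage
#'
#' Computes the summary statistics used for cross-stage comparison: mean,
#' median, quartiles and 5th/95th percentiles of the likelihood of success,
#' once over the phenology/space-weighted sample and once over all valid
#' pixels of the unweighted surface. The difference of the two means — the
#' mitigation index — measures how much the population's observed timing and
#' spatial distribution mitigate (positive) or aggravate (negative) thermal
#' impacts relative to uniform occupancy.
#'
#' @param weighted a `weighted_sample` from [weight_surface()], or a bare
#'   numeric vector of weighted likelihoods.
#' @param surface the matching `survival_surface` (or a numeric vector of
#'   unweighted likelihoods).
#' @return A two-row tibble (`weighting` = `"weighted"` / `"unweighted"`)
#'   with columns `stage`, `population`, `weighting`, `n`, `mean`, `median`,
#'   `q25`, `q75`, `p05`, `p95`, `n_valid`, `n_masked` and the
#'   `mitigation_index` repeated on both rows.
#' @export
summarize_comparison <- function(weighted, surface) {
  wv <- if (is.numeric(weighted)) weighted else weighted$likelihood_pct
  if (is.numeric(surface)) {
    uv <- surface
    n_valid <- length(uv)
    n_masked <- NA_integer_
    stage <- attr(weighted, "stage") %||% NA_character_
    population <- attr(weighted, "population") %||% NA_character_
  } else {
    stopifnot(inherits(surface, "survival_surface"))
    uv <- valid_values(surface)
    n_valid <- sum(surface$mask)
    n_masked <- sum(!surface$mask)
    stage <- surface$stage
    population <- surface$population
  }
  if (length(wv) == 0L || length(uv) == 0L) {
    abort("Cannot summarize an empty weighted sample or all-masked surface.")
  }
  stats_row <- function(v, label, n) {
    q <- quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
    tibble::tibble(
      stage = stage, population = population, weighting = label,
      n = n, mean = mean(v), median = q[3],
      q25 = q[2], q75 = q[4], p05 = q[1], p95 = q[5]
    )
  }
  out <- dplyr::bind_rows(
    stats_row(wv, "weighted", length(wv)),
    stats_row(uv, "unweighted", length(uv))
  )
  out$n_valid <- n_valid
  out$n_masked <- n_masked
  out$mitigation_index <- mean(wv) - mean(uv)
  out
}

#' Mitigation index of a comparison summary
#'
#' @param summary a tibble from [summarize_comparison()].
#' @return Weighted mean minus unweighted mean, percentage points.
#' @export
mitigation_index <- function(summary) {
  unique(summary$mitigation_index)
}

#' Violin comparison of weighted and unweighted likelihoods
#'
#' Renders the weighted samples against the unweighted pixel values per
#' stage/population, the standard display for cross-stage comparison.
#'
#' @param results a `thermal_run` from [run_pipeline()], or a tibble with
#'   columns `stage`, `population`, `weighting`, `likelihood_pct`.
#' @return A ggplot object.
#' @export
plot_comparison <- function(results) {
  df <- if (inherits(results, "thermal_run")) comparison_values(results) else tibble::as_tibble(results)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$stage, y = .data$likelihood_pct, fill = .data$weighting
  )) +
    ggplot2::geom_violin(position = ggplot2::position_dodge(width = 0.8),
                         scale = "width", trim = TRUE) +
    ggplot2::facet_wrap(~population) +
    ggplot2::scale_fill_manual(values = c(unweighted = "grey70", weighted = "#3182bd")) +
    ggplot2::labs(x = NULL, y = "Likelihood of success (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

# long tibble of weighted + unweighted values for plotting
comparison_values <- function(run) {
  purrr::map_dfr(run$populations, function(pop) {
    purrr::map_dfr(names(pop$surfaces), function(stg) {
      surf <- pop$surfaces[[stg]]
      ws <- pop$weighted[[stg]]
      dplyr::bind_rows(
        tibble::tibble(stage = stg, population = pop$name,
                       weighting = "weighted", likelihood_pct = ws$likelihood_pct),
        tibble::tibble(stage = stg, population = pop$name,
                       weighting = "unweighted", likelihood_pct = valid_values(surf))
      )
    })
  })
}

# ---- configuration ------------------------------------------------------

#' Read a pipeline configuration
#'
#' A run is fully described by one YAML (or list) configuration holding the
#' master seed, the river (a synthetic scenario or a monitor-record CSV plus
#' river length), and one block per population: run type, phenology and
#' spatial distributions (Gaussian parameters directly, or count-table CSVs
#' to fit), and optionally `phenology_from: <population>` for
#' reintroduction scenarios (donor timing on this river's grid and spatial
#' distributions). Model parameters default to the published values and can
#' be overridden under `params:`.
#'
#' @param x path to a YAML file, or a named list with the same structure.
#' @return The validated configuration list (class `thermal_config`).
#' @export
read_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  if (!is.list(cfg)) abort("Config must be a YAML file path or a list.")
  known <- c("seed", "river", "monitors", "populations", "stages", "params",
             "max_gap_days", "buffer_days")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0L) {
    abort(sprintf("Unknown config key(s): %s", paste(extra, collapse = ", ")))
  }
  if (is.null(cfg$seed)) abort("Config needs a `seed`.")
  if (is.null(cfg$river)) abort("Config needs a `river` block.")
  if (is.null(cfg$populations) || length(cfg$populations) == 0L) {
    abort("Config needs at least one population.")
  }
  cfg$stages <- cfg$stages %||% c("spawning", "egg_to_fry", "smolting")
  bad <- setdiff(cfg$stages, c("spawning", "egg_to_fry", "smolting"))
  if (length(bad) > 0L) abort(sprintf("Unknown stage(s): %s", paste(bad, collapse = ", ")))
  nm <- vapply(cfg$populations, function(p) p$name %||% NA_character_, character(1))
  if (anyNA(nm) || anyDuplicated(nm)) abort("Each population needs a unique `name`.")
  class(cfg) <- c("thermal_config", "list")
  cfg
}

config_grid <- function(cfg) {
  r <- cfg$river
  if (!is.null(r$records_csv)) {
    rec <- read_monitor_csv(r$records_csv)
    return(build_temperature_grid(rec, r$length_km,
                                  max_gap_days = cfg$max_gap_days %||% 30L))
  }
  scen <- river_scenario(
    river_length_km = r$length_km,
    start_date = r$start, end_date = r$end,
    mean_annual_temp = r$mean_annual_temp %||% 12,
    seasonal_amplitude = r$seasonal_amplitude %||% 6,
    peak_day = r$peak_day %||% 200,
    downstream_warming = r$downstream_warming %||% 0.05,
    daily_noise_sd = r$daily_noise_sd %||% 0.3,
    seed = derive_seed(cfg$seed, 1L)
  )
  field <- generate_true_field(scen)
  if (is.null(cfg$monitors)) return(field)
  rec <- sample_monitor_records(field, cfg$monitors$kms,
                                gaps = cfg$monitors$gaps)
  build_temperature_grid(rec, r$length_km,
                         max_gap_days = cfg$max_gap_days %||% 30L)
}

config_dists <- function(pop) {
  from_spec <- function(spec, axis, stage) {
    if (!is.null(spec$counts_csv)) {
      fit_gaussian(readr::read_csv(spec$counts_csv, show_col_types = FALSE),
                   stage = stage)
    } else if (!is.null(spec$counts)) {
      fit_gaussian(spec$counts, stage = stage)
    } else {
      gaussian_dist(spec$mean, spec$sd, axis = axis, stage = stage)
    }
  }
  list(
    arrival = from_spec(pop$arrival, "day", "arrival"),
    spawning = from_spec(pop$spawn, "day", "spawning"),
    emergence = from_spec(pop$emergence, "day", "emergence"),
    redds = from_spec(pop$redds, "km", "redds"),
    rearing = from_spec(pop$rearing, "km", "rearing")
  )
}

#' Run the full thermal-impacts pipeline
#'
#' Executes the whole analysis from one configuration: builds the
#' temperature grid, fits (or takes) each population's phenology and spatial
#' distributions, computes the requested per-pixel survival surfaces,
#' samples them at phenology/space-weighted pixels, and summarizes weighted
#' vs unweighted results per stage. All randomness derives from the single
#' master seed, so a rerun with the same configuration is identical.
#'
#' @param config a path to a YAML config, or a config list (see
#'   [read_config()]).
#' @return A `thermal_run` list: `grid`, per-population `dists`, `surfaces`,
#'   `weighted` samples, a combined `summary` tibble, and the resolved
#'   `config`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_config(config)
  grid <- config_grid(cfg)
  prm <- cfg$params %||% list()
  hold_p <- do.call(holding_params, prm$holding %||% list())
  emb_p <- do.call(embryo_params, prm$embryo %||% list())
  grw_p <- do.call(growth_params, prm$growth %||% list())
  buffer <- cfg$buffer_days %||% 30L

  dists_all <- setNames(
    lapply(cfg$populations, config_dists),
    vapply(cfg$populations, `[[`, character(1), "name")
  )

  populations <- purrr::imap(setNames(cfg$populations, names(dists_all)), function(pop, nm) {
    dists <- dists_all[[nm]]
    if (!is.null(pop$phenology_from)) {
      donor <- dists_all[[pop$phenology_from]]
      if (is.null(donor)) {
        abort(sprintf("`phenology_from` names unknown population '%s'.", pop$phenology_from))
      }
      # reintroduction mode: donor timing, host spatial distributions
      dists[c("arrival", "spawning", "emergence")] <-
        donor[c("arrival", "spawning", "emergence")]
    }
    budget <- do.call(
      energy_budget_params,
      c(list(run = pop$run %||% "spring"), prm$budget %||% list())
    )
    pop_i <- match(nm, names(dists_all))
    surfaces <- list()
    weighted <- list()
    if ("spawning" %in% cfg$stages) {
      surfaces$spawning <- spawning_success_surface(
        grid, dists$spawning, budget,
        hold_params = hold_p, arrival_phenology = dists$arrival,
        buffer_days = buffer, seed = derive_seed(cfg$seed, 10L + pop_i)
      )
      weighted$spawning <- weight_surface(
        surfaces$spawning, dists$arrival, dists$redds,
        seed = derive_seed(cfg$seed, 20L + pop_i)
      )
    }
    if ("egg_to_fry" %in% cfg$stages) {
      surfaces$egg_to_fry <- egg_to_fry_surface(grid, emb_p)
      weighted$egg_to_fry <- weight_surface(
        surfaces$egg_to_fry, dists$spawning, dists$redds,
        seed = derive_seed(cfg$seed, 30L + pop_i)
      )
    }
    if ("smolting" %in% cfg$stages) {
      surfaces$smolting <- smolting_success_surface(grid, grw_p)
      weighted$smolting <- weight_surface(
        surfaces$smolting, dists$emergence, dists$rearing,
        seed = derive_seed(cfg$seed, 40L + pop_i)
      )
    }
    list(name = nm, dists = dists, budget = budget,
         surfaces = surfaces, weighted = weighted)
  })

  summary <- purrr::map_dfr(populations, function(pop) {
    purrr::map_dfr(names(pop$surfaces), function(stg) {
      s <- summarize_comparison(pop$weighted[[stg]], pop$surfaces[[stg]])
      s$population <- pop$name
      s
    })
  })

  structure(
    list(grid = grid, populations = populations, summary = summary,
         params = list(holding = hold_p, embryo = emb_p, growth = grw_p),
         config = cfg),
    class = "thermal_run"
  )
}

#' @export
print.thermal_run <- function(x, ...) {
  cat("<thermal_run>\n")
  print(x$grid)
  cat(sprintf("  populations: %s\n",
              paste(names(x$populations), collapse = ", ")))
  cat(sprintf("  stages: %s\n",
              paste(unique(unlist(lapply(x$populations, function(p) names(p$surfaces)))),
                    collapse = ", ")))
  invisible(x)
}

#' @export
tidy.thermal_run <- function(x, ...) x$summary

#' @export
glance.thermal_run <- function(x, ...) {
  tibble::tibble(
    n_populations = length(x$populations),
    n_stages = length(unique(x$summary$stage)),
    n_km = length(x$grid$kms),
    n_days = length(x$grid$dates),
    seed = x$config$seed
  )
}

#' Write all outputs of a pipeline run
#'
#' Writes, under `dir`: the temperature grid and every surface as
#' long-format CSVs, dense heatmap tables, weighted-sample CSVs, the summary
#' table, and a copy of the resolved configuration (YAML) so the run can be
#' reproduced.
#'
#' @param run a `thermal_run`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "thermal_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_grid_csv(run$grid, file.path(dir, "temperature_grid.csv"))
  export_heatmap_table(run$grid, file.path(dir, "temperature_matrix.csv"))
  for (pop in run$populations) {
    for (stg in names(pop$surfaces)) {
      base <- sprintf("%s_%s", pop$name, stg)
      write_grid_csv(pop$surfaces[[stg]], file.path(dir, paste0(base, "_surface.csv")))
      export_heatmap_table(pop$surfaces[[stg]], file.path(dir, paste0(base, "_matrix.csv")))
      readr::write_csv(tibble::as_tibble(pop$weighted[[stg]]),
                       file.path(dir, paste0(base, "_weighted.csv")))
    }
  }
  readr::write_csv(run$summary, file.path(dir, "summary.csv"))
  yaml::write_yaml(unclass(run$config), file.path(dir, "config_resolved.yaml"))
  invisible(dir)
}
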