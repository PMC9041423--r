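# shared axis-column detection for count tables
count_axis_col <- function(counts) {
  hit <- intersect(c("julian_day", "river_km"), names(counts))
  if (length(hit) != 1L) {
    abort("Count table must have exactly one of `julian_day` or `river_km`.")
  }
  hit
}

#' Normalize survey counts to per-year percentages
#'
#' Converts raw counts into percentages of that year's total, so each survey
#' year contributes equal weight to the fitted distribution regardless of
#' that year's population size. Years with a zero total are dropped with a
#' warning.
#'
#' @param counts tibble with `julian_day` or `river_km`, `count`, `year`.
#' @return The table with a `pct` column; each retained year's `pct` sums
#'   to 100.
#' @export
normalize_counts <- function(counts) {
  counts <- tibble::as_tibble(counts)
  count_axis_col(counts)
  if (!all(c("count", "year") %in% names(counts))) {
    abort("Count table must have `count` and `year` columns.")
  }
  totals <- dplyr::summarise(dplyr::group_by(counts, .data$year),
                             total = sum(.data$count), .groups = "drop")
  zero <- totals$year[totals$total <= 0]
  if (length(zero) > 0L) {
    warn(sprintf("Dropping year(s) with zero total count: %s",
                 paste(zero, collapse = ", ")))
    counts <- counts[!counts$year %in% zero, , drop = FALSE]
  }
  if (nrow(counts) == 0L) abort("No year with a positive total count.")
  out <- dplyr::mutate(dplyr::group_by(counts, .data$year),
                       pct = 100 * .data$count / sum(.data$count))
  dplyr::ungroup(out)
}

#' Gaussian phenology / spatial distribution
#'
#' A fitted (or directly specified) normal distribution over Julian day
#' (phenology of arrival, spawning or emergence) or river-km (redd or
#' rearing locations).
#'
#' @param mean,sd location and scale on the axis; `sd > 0`.
#' @param axis `"day"` or `"km"`.
#' @param stage optional life-stage label.
#' @param n_years number of survey years behind the fit (metadata).
#' @return A `gaussian_dist` object.
#' @export
gaussian_dist <- function(mean, sd, axis = c("day", "km"), stage = NA_character_,
                          n_years = NA_integer_) {
  axis <- match.arg(axis)
  assert_scalar_number(mean, "mean")
  assert_scalar_number(sd, "sd", positive = TRUE)
  if (axis == "day" && (mean < 1 || mean > 366)) {
    abort("A phenology mean must be a Julian day in 1..366.")
  }
  structure(
    list(mean = mean, sd = sd, axis = axis, stage = stage,
         n_years = as.integer(n_years)),
    class = "gaussian_dist"
  )
}

check_gaussian_dist <- function(x, axis = NULL) {
  if (!inherits(x, "gaussian_dist")) abort("Expected a `gaussian_dist` object.")
  if (!is.null(axis) && !identical(x$axis, axis)) {
    abort(sprintf("Expected a distribution on the %s axis.", axis))
  }
  invisible(x)
}

#' @export
print.gaussian_dist <- function(x, ...) {
  cat(sprintf("<gaussian_dist %s%s> mean = %.2f, sd = %.2f\n",
              x$axis, if (is.na(x$stage)) "" else paste0(": ", x$stage),
              x$mean, x$sd))
  invisible(x)
}

#' @export
tidy.gaussian_dist <- function(x, ...) {
  tibble::tibble(term = c("mean", "sd"), estimate = c(x$mean, x$sd))
}

#' @export
glance.gaussian_dist <- function(x, ...) {
  tibble::tibble(mean = x$mean, sd = x$sd, axis = x$axis,
                 stage = x$stage, n_years = x$n_years)
}

#' Fit a Gaussian distribution to a count table
#'
#' Counts are first normalized per year ([normalize_counts()]) so every year
#' weighs equally, then the Gaussian mean and sd are the percentage-weighted
#' first and second central moments of the axis values (method of moments,
#' exact for the Gaussian family on weighted data).
#'
#' @param counts tibble with `julian_day` or `river_km`, `count`, `year`.
#' @param stage optional life-stage label to attach.
#' @param sd_override optional fixed sd for degenerate (single support
#'   point) tables.
#' @return A [gaussian_dist()].
#' @export
fit_gaussian <- function(counts, stage = NA_character_, sd_override = NULL) {
  counts <- normalize_counts(counts)
  axis_col <- count_axis_col(counts)
  x <- counts[[axis_col]]
  w <- counts$pct
  keep <- w > 0
  x <- x[keep]
  w <- w[keep]
  mu <- sum(w * x) / sum(w)
  if (length(unique(x)) < 2L) {
    if (is.null(sd_override)) {
      abort(paste0(
        "Degenerate count table (single support point); pass `sd_override` ",
        "to fix the spread."
      ))
    }
    s <- sd_override
  } else {
    s <- sqrt(sum(w * (x - mu)^2) / sum(w))
  }
  gaussian_dist(mu, s,
    axis = if (axis_col == "julian_day") "day" else "km",
    stage = stage, n_years = length(unique(counts$year))
  )
}

#' Sample a survival surface at phenology- and space-weighted pixels
#'
#' Draws (Julian day, river-km) pairs independently from the phenology and
#' spatial distributions, rounds them to grid cells, and reads the surface
#' value at each draw that lands on a valid pixel. The number of draws before
#' filtering equals the total pixel count of the surface (the weighted sample
#' has as many replicates as the unweighted matrix); draws on masked or
#' off-grid cells are dropped, not redrawn.
#'
#' @param surface a `survival_surface`.
#' @param phen a [gaussian_dist()] over Julian day.
#' @param spat a [gaussian_dist()] over river-km.
#' @param seed integer seed.
#' @return A `weighted_sample`: tibble with `julian_day`, `river_km`,
#'   `likelihood_pct`, plus attributes `stage`, `population`, `n_requested`.
#' @export
weight_surface <- function(surface, phen, spat, seed) {
  stopifnot(inherits(surface, "survival_surface"))
  check_gaussian_dist(phen, "day")
  check_gaussian_dist(spat, "km")
  if (missing(seed) || is.null(seed)) abort("`seed` is required.")
  n <- length(surface$kms) * length(surface$dates)
  draws <- with_seed(seed, {
    tibble::tibble(
      julian_day = round(rnorm(n, phen$mean, phen$sd)),
      river_km = round_km(rnorm(n, spat$mean, spat$sd))
    )
  })
  ydays <- jday(surface$dates)
  yrs <- as.integer(format(surface$dates, "%Y"))
  uyrs <- unique(yrs)
  if (length(uyrs) == 1L) {
    col_of <- match(draws$julian_day, ydays)
  } else {
    # phenology replicates across grid years: pick a year uniformly per draw
    yr_draw <- with_seed(derive_seed(seed, 2L), sample(uyrs, n, replace = TRUE))
    key <- paste(yr_draw, draws$julian_day)
    col_of <- match(key, paste(yrs, ydays))
  }
  row_of <- match(draws$river_km, surface$kms)
  ok <- !is.na(col_of) & !is.na(row_of)
  idx <- cbind(row_of[ok], col_of[ok])
  valid <- surface$mask[idx]
  kept <- draws[ok, ][valid, ]
  kept$likelihood_pct <- surface$values[idx][valid]
  if (nrow(kept) < 0.01 * n) {
    abort("Fewer than 1% of draws landed on valid pixels; distributions and grid are mismatched.")
  }
  structure(
    kept,
    stage = surface$stage, population = surface$population,
    n_requested = n, seed = as.integer(seed),
    class = c("weighted_sample", class(kept))
  )
}
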