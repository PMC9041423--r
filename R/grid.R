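#' Temperature and survival grids
#'
#' A `temp_grid` holds mean daily stream temperature (degrees C) on a
#' 1 km x 1 day lattice: rows are integer river-km (0 at the confluence,
#' increasing upstream towards the dam), columns are calendar days. A logical
#' `mask` marks cells with valid data; cells that could not be interpolated
#' (outside the bracketing monitors on a date) are invalid. A
#' `survival_surface` shares the axes and mask convention but stores the
#' likelihood of success (percent, 0-100) for one life stage.
#'
#' @param kms integer vector of river-km positions (sorted ascending).
#' @param dates vector of `Date`s, consecutive days, sorted ascending.
#' @param values numeric matrix, `length(kms)` rows x `length(dates)` columns.
#' @param mask logical matrix of the same shape; `TRUE` where valid.
#' @return A `temp_grid` object.
#' @export
temp_grid <- function(kms, dates, values, mask = NULL) {
  kms <- as.integer(kms)
  dates <- as.Date(dates)
  if (length(kms) == 0L || length(dates) == 0L) {
    abort("A temperature grid needs at least one km and one date.")
  }
  if (is.unsorted(kms, strictly = TRUE)) abort("`kms` must be strictly increasing.")
  if (is.unsorted(dates, strictly = TRUE)) abort("`dates` must be strictly increasing.")
  values <- as.matrix(values)
  if (!all(dim(values) == c(length(kms), length(dates)))) {
    abort("`values` must be a length(kms) x length(dates) matrix.")
  }
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(values))) abort("`mask` must match `values` in shape.")
  mask <- mask & !is.na(values)
  if (any(!is.finite(values[mask]))) abort("Valid cells must hold finite temperatures.")
  structure(
    list(kms = kms, dates = dates, values = values, mask = mask),
    class = "temp_grid"
  )
}

new_survival_surface <- function(grid_like, values, mask, stage, population = NA_character_) {
  values[!mask] <- NA_real_
  if (any(values[mask] < -1e-9 | values[mask] > 100 + 1e-9)) {
    abort("Survival likelihoods must lie in [0, 100].")
  }
  values[mask] <- pmin(pmax(values[mask], 0), 100)
  structure(
    list(
      kms = grid_like$kms, dates = grid_like$dates,
      values = values, mask = mask,
      stage = stage, population = population
    ),
    class = c("survival_surface", "temp_grid")
  )
}

#' @export
print.temp_grid <- function(x, ...) {
  kind <- if (inherits(x, "survival_surface")) {
    sprintf("<survival_surface: %s%s>", x$stage,
            if (is.na(x$population)) "" else paste0(", ", x$population))
  } else {
    "<temp_grid>"
  }
  cat(kind, "\n", sep = "")
  cat(sprintf(
    "  %d km (%d-%d) x %d days (%s to %s); %.1f%% of cells valid\n",
    length(x$kms), min(x$kms), max(x$kms), length(x$dates),
    format(min(x$dates)), format(max(x$dates)),
    100 * mean(x$mask)
  ))
  invisible(x)
}

#' @export
dim.temp_grid <- function(x) dim(x$values)

#' Tidy a grid into long format
#'
#' One row per (km, date) cell; invalid cells carry `NA` values and
#' `valid = FALSE`.
#'
#' @param x a `temp_grid` or `survival_surface`.
#' @param ... unused.
#' @return A tibble with columns `km`, `date`, `valid` and either `temp_c`
#'   or `likelihood_pct` (plus `stage`, `population` for surfaces).
#' @export
tidy.temp_grid <- function(x, ...) {
  out <- tibble::tibble(
    km = rep(x$kms, times = length(x$dates)),
    date = rep(x$dates, each = length(x$kms)),
    temp_c = as.vector(ifelse(x$mask, x$values, NA_real_)),
    valid = as.vector(x$mask)
  )
  out
}

#' @export
tidy.survival_surface <- function(x, ...) {
  tibble::tibble(
    km = rep(x$kms, times = length(x$dates)),
    date = rep(x$dates, each = length(x$kms)),
    stage = x$stage,
    population = x$population,
    likelihood_pct = as.vector(ifelse(x$mask, x$values, NA_real_)),
    valid = as.vector(x$mask)
  )
}

#' @export
as_tibble.temp_grid <- function(x, ...) tidy(x, ...)

#' One-line grid summary
#'
#' @param x a `temp_grid` or `survival_surface`.
#' @param ... unused.
#' @return A one-row tibble with axis extents, valid/masked cell counts and
#'   the mean over valid cells.
#' @export
glance.temp_grid <- function(x, ...) {
  tibble::tibble(
    n_km = length(x$kms),
    n_days = length(x$dates),
    n_valid = sum(x$mask),
    n_masked = sum(!x$mask),
    mean_valid = if (any(x$mask)) mean(x$values[x$mask]) else NA_real_
  )
}

#' Values at valid pixels
#'
#' The unweighted vector of a grid's valid-cell values (likelihoods for a
#' surface, temperatures for a grid), the counterpart of a weighted sample.
#'
#' @param x a `temp_grid` or `survival_surface`.
#' @return A numeric vector, one entry per valid pixel.
#' @export
valid_values <- function(x) x$values[x$mask]

#' Heatmap display of a grid
#'
#' Renders the km x date lattice with `ggplot2::geom_raster()`; masked cells
#' are left blank, matching the convention of plotting no-data pixels in grey.
#'
#' @param object a `temp_grid` or `survival_surface`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.temp_grid <- function(object, ...) {
  df <- tidy(object)
  fill_col <- if (inherits(object, "survival_surface")) "likelihood_pct" else "temp_c"
  lab <- if (identical(fill_col, "temp_c")) "Temp (°C)" else "Likelihood (%)"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$km)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data[[fill_col]])) +
    ggplot2::scale_fill_viridis_c(na.value = "grey80", name = lab) +
    ggplot2::labs(x = NULL, y = "River km (0 = confluence)") +
    ggplot2::theme_minimal()
}

#' Write and read a dense heatmap table
#'
#' Exports a grid as a dense CSV matrix (km rows, date columns) with the
#' string sentinel `"NA"` for masked cells, so a masked pixel can never be
#' confused with a true 0. `read_heatmap_table()` round-trips the file.
#'
#' @param x a `temp_grid` or `survival_surface`.
#' @param path file path.
#' @return `export_heatmap_table()` returns `path` invisibly;
#'   `read_heatmap_table()` returns a `temp_grid` (or `survival_surface` when
#'   stage metadata is present in the header comment).
#' @export
export_heatmap_table <- function(x, path) {
  vals <- ifelse(x$mask, x$values, NA_real_)
  df <- as.data.frame(vals)
  names(df) <- format(x$dates)
  df <- cbind(km = x$kms, df)
  header <- if (inherits(x, "survival_surface")) {
    sprintf("# survival_surface stage=%s population=%s", x$stage, x$population)
  } else {
    "# temp_grid"
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname export_heatmap_table
#' @export
read_heatmap_table <- function(path) {
  header <- readLines(path, n = 1L)
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  kms <- as.integer(df$km)
  dates <- as.Date(names(df)[-1])
  vals <- as.matrix(df[, -1, drop = FALSE])
  dimnames(vals) <- NULL
  if (grepl("^# survival_surface", header)) {
    stage <- sub(".*stage=(\\S+).*", "\\1", header)
    population <- sub(".*population=(\\S+).*", "\\1", header)
    g <- list(kms = kms, dates = dates)
    new_survival_surface(g, vals, !is.na(vals), stage = stage,
                         population = if (population == "NA") NA_character_ else population)
  } else {
    temp_grid(kms, dates, vals)
  }
}

#' Write a grid as a long-format CSV
#'
#' Columns `km, date, temp_c, valid` (or `km, date, stage, population,
#' likelihood_pct, valid` for surfaces), dates ISO-8601.
#'
#' @param x a `temp_grid` or `survival_surface`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(x, path) {
  readr::write_csv(tidy(x), path, na = "NA")
  invisible(path)
}
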