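# internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom rlang abort warn
NULL

# Julian day 1..365/366
jday <- function(dates) {
  as.POSIXlt(dates)$yday + 1L
}

# Deterministic per-pixel substream seed below 2^31, never 0.
# mixes a master seed with one or two stream indices
derive_seed <- function(seed, i, j = 0L) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) + 1
  s <- (s * 48271 + as.numeric(i) * 10007 + as.numeric(j) * 101159) %% m
  as.integer(s + 1)
}

# run an expression with a local RNG state (no global side effects)
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# round river-km to the grid; ties go half away from the confluence (upstream)
round_km <- function(km) {
  as.integer(floor(km + 0.5))
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}
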