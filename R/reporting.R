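## Uncertainty propagation and presentation conventions: 100 draws by
## default, 95% uncertainty intervals as the 2.5th/97.5th percentiles across
## draws, counts to three significant figures, rates and percentages to one
## decimal place (round half away from zero).

#' Generate Monte-Carlo draws around point estimates
#'
#' Draws are normal in a declared transformed space: `identity` for
#' unbounded quantities, `log` for rates (keeps draws positive), `logit` for
#' proportions (keeps draws in (0,1)). `uncertainty` is the standard
#' deviation in that transformed space.
#'
#' @param mean numeric vector of cell means (natural scale).
#' @param uncertainty standard deviation in transformed space; scalar or
#'   vector.
#' @param n number of draws (default 100).
#' @param seed integer seed; draws are deterministic given the seed.
#' @param transform one of "identity", "log", "logit".
#' @param keys optional tibble of demographic keys (defaults to a row index).
#' @return A [drawset].
#' @export
make_draws <- function(mean, uncertainty, n = 100L, seed = 1L,
                       transform = c("identity", "log", "logit"),
                       keys = NULL) {
  transform <- match.arg(transform)
  if (n < 2) dm_abort("at least 2 draws are required", "dm_config_error")
  if (is.null(keys)) keys <- tibble::tibble(cell = seq_along(mean))
  fwd <- switch(transform, identity = identity, log = log, logit = qlogis)
  inv <- switch(transform, identity = identity, log = exp, logit = plogis)
  m <- length(mean)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  z <- matrix(rnorm(m * n), nrow = m)
  draws <- inv(fwd(mean) + z * uncertainty)
  drawset(keys, draws)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Summarise draws into mean and 95% uncertainty interval
#'
#' The interval is the 2.5th and 97.5th percentile across draws, using
#' linear interpolation between order statistics (`stats::quantile` type 7).
#'
#' @param ds a [drawset].
#' @return A tibble: key columns plus `mean`, `lower`, `upper`. `lower <=
#'   upper` always holds; the mean is not forced inside the band.
#' @export
summarise_draws <- function(ds) {
  q <- t(apply(ds$draws, 1, quantile, probs = c(0.025, 0.975),
               names = FALSE, type = 7))
  dplyr::bind_cols(
    ds$keys,
    tibble::tibble(mean = rowMeans(ds$draws), lower = q[, 1], upper = q[, 2])
  )
}

## Round half away from zero at d decimals (R's round() is half-to-even).
round_half_away <- function(x, d = 0) {
  sign(x) * floor(abs(x) * 10^d + 0.5) / 10^d
}

#' Format a value under the reporting conventions
#'
#' Counts are reported to three significant figures; rates and percentages
#' to one decimal place, rounding half away from zero.
#'
#' @param value finite numeric scalar or vector.
#' @param kind one of "count", "rate", "percent".
#' @return character vector.
#' @export
format_value <- function(value, kind = c("count", "rate", "percent")) {
  kind <- match.arg(kind)
  if (any(!is.finite(value))) {
    dm_abort("non-finite value cannot be formatted", "dm_config_error")
  }
  if (kind == "count") {
    out <- vapply(value, function(v) {
      if (v == 0) return("0")
      format(signif(v, 3), big.mark = " ", scientific = FALSE, trim = TRUE)
    }, character(1))
  } else {
    out <- sprintf("%.1f", round_half_away(value, 1))
  }
  out
}

#' Percentage of a count over a denominator
#'
#' The "89 (43.6%) of 204 locations" convention: numerator/denominator x 100
#' at one decimal place (half away from zero).
#'
#' @param numerator,denominator counts; denominator must be positive.
#' @return numeric percent rounded to one decimal.
#' @export
percent_of <- function(numerator, denominator) {
  if (any(denominator <= 0)) {
    dm_abort("denominator must be positive", "dm_config_error")
  }
  round_half_away(numerator / denominator * 100, 1)
}

#' Draw-wise percentage change between two DrawSets
#'
#' Computed per draw as (v1 - v0)/v0 x 100 and then summarised; this is not
#' the same as the change between rounded summary means when draws are
#' skewed, and the draw-wise rule is the one used throughout.
#'
#' @param v0,v1 aligned [drawset]s; every baseline draw must be positive.
#' @return A tibble from [summarise_draws] of the percent-change draws.
#' @export
percentage_change <- function(v0, v1) {
  if (any(v0$draws <= 0)) {
    dm_abort("percentage change undefined: nonpositive baseline draw",
             "dm_config_error")
  }
  summarise_draws(ds_combine(v0, v1, function(a, b) (b - a) / a * 100))
}
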