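## Single-level penalised fit of the illness-death rates to noisy prevalence
## datapoints and a cause-specific mortality series: weighted least squares
## in prevalence and CSMR space plus a squared-second-difference smoothness
## penalty on the log-rate knot values, with box constraints (remission cap,
## positivity via the log parameterisation). Uncertainty by nonparametric
## bootstrap of the prevalence datapoints, refitting from the point estimate.

## Knot layout: one knot per two age groups, linear interpolation in group
## index on the log scale.
knot_index <- function(G) {
  k <- seq(1, G, by = 2)
  if (k[length(k)] != G) k <- c(k, G)
  k
}

second_diff_penalty <- function(v) {
  if (length(v) < 3) return(0)
  sum(diff(v, differences = 2)^2)
}

#' Fit illness-death rates to prevalence and CSMR data
#'
#' Estimates age curves of incidence, excess mortality and (optionally)
#' remission for one demographic stratum by minimising a penalised weighted
#' least-squares objective: squared misfit of modelled prevalence to the
#' datapoints and of modelled CSMR to the mortality series (inverse-variance
#' weights), plus a smoothness penalty on second differences of the log-rate
#' knots. The modelled prevalence/CSMR come from [solve_illness_death], so
#' the returned bundle is self-consistent by construction. Remission is
#' either fixed (type 1: 0) or estimated under a hard cap (total diabetes:
#' 0.01/yr).
#'
#' @param prev_data tibble of prevalence datapoints with columns
#'   `age_start`, `age_end`, `value`, `se` (reference case definition).
#' @param csmr_data tibble with `age_start` and `value` (deaths per
#'   person-year), one row per age group; optional `se`.
#' @param age_edges age-group lower edges.
#' @param background_mort per-age-group background mortality (all-cause
#'   minus diabetes CSMR, floored at 1e-6/yr by the caller).
#' @param remission_cap upper bound on remission (per year), default 0.01.
#' @param fix_remission if non-NULL, remission is fixed at this value (use 0
#'   for type 1) instead of estimated.
#' @param smoothness penalty weight on squared second differences of log
#'   rates (default 0.1).
#' @param n_boot bootstrap replicates for draws (0 = point estimate only).
#' @param seed seed for the bootstrap resampling.
#' @param maxit optimiser iteration cap for the point fit; bootstrap refits
#'   warm-start from the point estimate with `boot_maxit` iterations.
#' @param boot_maxit iteration cap for warm-started bootstrap refits.
#' @return An object of class `rate_fit`: list with `bundle` (the fitted
#'   rate tibble from [solve_illness_death]), `prev_draws` and `csmr_draws`
#'   (age-group x replicate matrices, present when `n_boot > 0`),
#'   `convergence`, `objective`.
#' @export
fit_rates <- function(prev_data, csmr_data, age_edges, background_mort,
                      remission_cap = 0.01, fix_remission = NULL,
                      smoothness = 0.1, n_boot = 0L, seed = 1L,
                      maxit = 200L, boot_maxit = 40L) {
  check_age_edges(age_edges)
  G <- length(age_edges)
  if (is.null(csmr_data) || nrow(csmr_data) == 0) {
    dm_abort("csmr series required", "dm_config_error")
  }
  if (nrow(prev_data) < 1) {
    dm_abort("at least one prevalence datapoint is required",
             "dm_config_error")
  }
  if (!is.null(remission_cap) && remission_cap < 0) {
    dm_abort("remission cap must be non-negative", "dm_config_error")
  }
  estimate_r <- is.null(fix_remission)

  ## map datapoints to age groups by interval midpoint
  grp_of <- function(a_start, a_end) {
    mid <- age_midpoint(a_start, a_end)
    findInterval(mid, age_edges)
  }
  pg <- grp_of(prev_data$age_start, prev_data$age_end)
  pv <- prev_data$value
  pw <- 1 / pmax(prev_data$se, 1e-4)^2
  cg <- findInterval(csmr_data$age_start + 1e-9, age_edges)
  cv <- csmr_data$value
  cse <- if ("se" %in% names(csmr_data)) csmr_data$se else
    pmax(0.1 * cv, 1e-6)
  cw <- 1 / pmax(cse, 1e-6)^2

  kidx <- knot_index(G)
  K <- length(kidx)
  nblk <- if (estimate_r) 3L else 2L
  LOG_LO <- log(1e-8)

  ## precomputed linear-interpolation weights from knots to age groups
  seg <- pmin(findInterval(seq_len(G), kidx), K - 1L)
  wk <- (seq_len(G) - kidx[seg]) / (kidx[seg + 1L] - kidx[seg])
  expand <- function(v) exp(v[seg] * (1 - wk) + v[seg + 1L] * wk)
  r_fixed <- if (!estimate_r) rep(fix_remission, G)

  decode <- function(theta) {
    list(i = expand(theta[1:K]),
         f = expand(theta[(K + 1):(2 * K)]),
         r = if (estimate_r) expand(theta[(2 * K + 1):(3 * K)]) else r_fixed)
  }

  widths <- c(diff(age_edges), 5)
  objective <- function(theta, pv_w = pw, pv_v = pv) {
    rt <- decode(theta)
    p <- illness_death_core(rt$i, rt$r, rt$f, background_mort, widths)$p_mid
    misfit <- sum(pv_w * (p[pg] - pv_v)^2) +
      sum(cw * (p[cg] * rt$f[cg] - cv)^2)
    pen <- second_diff_penalty(theta[1:K]) +
      second_diff_penalty(theta[(K + 1):(2 * K)])
    if (estimate_r) pen <- pen + second_diff_penalty(theta[(2 * K + 1):(3 * K)])
    misfit + smoothness * pen
  }

  ## start values: crude inversions of the data
  p_obs <- pmax(pv, 1e-4)
  f0 <- log(pmax(stats::median(cv) / stats::median(p_obs), 1e-4))
  i0 <- log(pmax(stats::median(p_obs) / mean(age_midpoint(
    prev_data$age_start, prev_data$age_end)), 1e-5))
  start <- c(rep(i0, K), rep(f0, K))
  upper <- c(rep(log(5), 2 * K))
  if (estimate_r) {
    start <- c(start, rep(log(max(remission_cap / 2, 1e-7)), K))
    upper <- c(upper, rep(log(max(remission_cap, 1e-8)), K))
  }
  lower <- rep(LOG_LO, length(start))

  run_fit <- function(par0, w, v, iters) {
    optim(par0, objective, method = "L-BFGS-B",
          lower = lower, upper = pmin(upper, 5),
          control = list(maxit = iters, factr = 1e9),
          pv_w = w, pv_v = v)
  }

  fit <- run_fit(start, pw, pv, maxit)
  if (!fit$convergence %in% c(0L, 1L)) {
    dm_abort(sprintf("rate fit did not converge (code %d: %s)",
                     fit$convergence, fit$message), "dm_fit_error")
  }
  rt <- decode(fit$par)
  bundle <- solve_illness_death(rt$i, rt$r, rt$f, background_mort, age_edges)

  prev_draws <- csmr_draws <- NULL
  if (n_boot > 0) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
    n <- length(pv)
    prev_draws <- matrix(0, G, n_boot)
    csmr_draws <- matrix(0, G, n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      ## resampling as weights keeps the design fixed (warm start stays close)
      wb <- tabulate(idx, nbins = n) * pw
      fb <- run_fit(fit$par, wb, pv, boot_maxit)
      rb <- decode(fb$par)
      sb <- solve_illness_death(rb$i, rb$r, rb$f, background_mort, age_edges)
      prev_draws[, b] <- sb$prevalence
      csmr_draws[, b] <- sb$csmr
    }
  }

  structure(list(bundle = bundle, prev_draws = prev_draws,
                 csmr_draws = csmr_draws, convergence = fit$convergence,
                 objective = fit$value),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit: %d age groups, objective %.4g>\n",
              nrow(x$bundle), x$objective))
  invisible(x)
}
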