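## Comparative risk assessment: relative-risk curves (piecewise-linear on a
## stated exposure grid, or categorical), exposure distributions, TMRELs,
## population attributable fractions, attributable DALYs, and the 16-risk
## synthetic registry (air temperature risks attach to both diabetes types;
## every other risk attaches to type 2 only).

#' Construct a relative-risk curve
#'
#' @param grid for continuous risks: exposure grid (risk-specific units),
#'   strictly increasing; for categorical risks: category labels.
#' @param rr positive relative risks at the grid points (piecewise-linear
#'   between) or per category.
#' @param kind "continuous" or "categorical".
#' @return Object of class `rr_curve`.
#' @export
rr_curve <- function(grid, rr, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (any(rr <= 0)) dm_abort("RR must be positive on the grid",
                             "dm_domain_error")
  if (kind == "continuous" && any(diff(grid) <= 0)) {
    dm_abort("exposure grid must be strictly increasing", "dm_config_error")
  }
  structure(list(grid = grid, rr = rr, kind = kind, tmrel = NULL),
            class = "rr_curve")
}

rr_at <- function(curve, x) {
  if (curve$kind == "categorical") {
    idx <- match(x, curve$grid)
    if (anyNA(idx)) dm_abort("unknown exposure category", "dm_config_error")
    return(curve$rr[idx])
  }
  approx(curve$grid, curve$rr, xout = x, rule = 2)$y
}

## mean RR over an interval of the piecewise-linear curve (trapezoid)
rr_interval_mean <- function(curve, lo, hi) {
  xs <- sort(unique(c(lo, hi, curve$grid[curve$grid > lo & curve$grid < hi])))
  ys <- rr_at(curve, xs)
  sum(diff(xs) * (head(ys, -1) + ys[-1]) / 2) / (hi - lo)
}

#' Normalise a relative-risk curve at the TMREL
#'
#' Divides the whole curve by its value at the theoretical minimum risk
#' exposure level. A point TMREL uses the interpolated RR there; an interval
#' TMREL (length-2 numeric) uses the mean RR over the interval (uniform
#' averaging). After normalisation RR(TMREL) = 1.
#'
#' @param curve an [rr_curve].
#' @param tmrel a point (scalar or single category label) or an interval
#'   (length-2 numeric) on the exposure axis; must lie within the grid.
#' @return The normalised `rr_curve`, with the TMREL recorded.
#' @export
normalize_rr <- function(curve, tmrel) {
  if (curve$kind == "continuous") {
    rng <- range(curve$grid)
    if (any(tmrel < rng[1] | tmrel > rng[2])) {
      dm_abort("TMREL lies outside the exposure grid", "dm_config_error")
    }
    ref <- if (length(tmrel) == 2) {
      rr_interval_mean(curve, min(tmrel), max(tmrel))
    } else rr_at(curve, tmrel)
  } else {
    ref <- rr_at(curve, tmrel)
  }
  curve$rr <- curve$rr / ref
  curve$tmrel <- tmrel
  curve
}

rr_at_tmrel <- function(curve) {
  if (curve$kind == "continuous" && length(curve$tmrel) == 2) {
    rr_interval_mean(curve, min(curve$tmrel), max(curve$tmrel))
  } else rr_at(curve, curve$tmrel)
}

#' Construct an exposure distribution
#'
#' @param x for categorical: named probabilities summing to 1; for
#'   continuous: density values on `grid` integrating (trapezoid) to 1
#'   within 1e-6.
#' @param grid exposure grid for continuous distributions.
#' @param kind "continuous" or "categorical".
#' @return Object of class `exposure_dist`.
#' @export
exposure_dist <- function(x, grid = NULL,
                          kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (kind == "categorical") {
    if (abs(sum(x) - 1) > 1e-6) {
      dm_abort("category probabilities must sum to 1", "dm_config_error")
    }
  } else {
    mass <- sum(diff(grid) * (head(x, -1) + x[-1]) / 2)
    if (abs(mass - 1) > 1e-6) {
      dm_abort("density must integrate to 1 on the grid", "dm_config_error")
    }
  }
  structure(list(x = x, grid = grid, kind = kind), class = "exposure_dist")
}

## discretised, renormalised normal density on a grid
normal_exposure <- function(grid, mean, sd) {
  d <- stats::dnorm(grid, mean, sd)
  mass <- sum(diff(grid) * (head(d, -1) + d[-1]) / 2)
  exposure_dist(d / mass, grid, "continuous")
}

#' Population attributable fraction
#'
#' PAF = (E\[RR\] - 1) / E\[RR\] under the exposure distribution, with the
#' curve normalised so RR(TMREL) = 1: the proportional reduction in burden
#' if everyone moved to the TMREL. Categorical: E\[RR\] = sum p_i RR_i;
#' continuous: trapezoid integral of density x RR on the grid. Negative
#' PAFs are allowed (exposure protective relative to the TMREL).
#'
#' @param exposure an [exposure_dist].
#' @param curve a TMREL-normalised [rr_curve] (checked to 1e-9).
#' @return PAF in (-1, 1).
#' @export
compute_paf <- function(exposure, curve) {
  if (is.null(curve$tmrel) || abs(rr_at_tmrel(curve) - 1) > 1e-9) {
    dm_abort("RR curve is not normalised at the TMREL", "dm_domain_error")
  }
  if (exposure$kind != curve$kind) {
    dm_abort("exposure and RR curve kinds differ", "dm_config_error")
  }
  mean_rr <- if (exposure$kind == "categorical") {
    sum(exposure$x * rr_at(curve, names(exposure$x)))
  } else {
    rr <- rr_at(curve, exposure$grid)
    g <- exposure$grid
    sum(diff(g) * (head(exposure$x * rr, -1) + (exposure$x * rr)[-1]) / 2)
  }
  (mean_rr - 1) / mean_rr
}

#' Attributable burden
#'
#' Attributable DALYs = PAF x DALYs, draw-wise on aligned grids.
#'
#' @param paf a [drawset] of PAFs.
#' @param dalys a [drawset] of DALYs.
#' @return A [drawset].
#' @export
attributable_burden <- function(paf, dalys) ds_combine(paf, dalys, `*`)

#' Aggregate PAFs across risks
#'
#' Combined PAF = 1 - prod_j (1 - PAF_j), draw-wise: the independence
#' approximation (no mediation adjustment between overlapping risks).
#'
#' @param pafs list of aligned PAF [drawset]s, all values < 1.
#' @return A [drawset].
#' @export
aggregate_pafs <- function(pafs) {
  if (any(vapply(pafs, function(p) any(p$draws >= 1), logical(1)))) {
    dm_abort("PAF >= 1 cannot be aggregated", "dm_domain_error")
  }
  out <- ds_map(pafs[[1]], function(d) 1 - d)
  if (length(pafs) > 1) {
    for (p in pafs[-1]) out <- ds_combine(out, p, function(a, b) a * (1 - b))
  }
  ds_map(out, function(d) 1 - d)
}

#' Draw-wise percentage change in PAF between two periods
#'
#' @param paf_t0,paf_t1 aligned PAF [drawset]s; baseline draws must be
#'   positive.
#' @return A [drawset] of percent changes (summarise with
#'   [summarise_draws]).
#' @export
paf_percentage_change <- function(paf_t0, paf_t1) {
  if (any(paf_t0$draws <= 0)) {
    dm_abort("baseline PAF draw <= 0: percentage change undefined",
             "dm_config_error")
  }
  ds_combine(paf_t0, paf_t1, function(a, b) (b - a) / a * 100)
}

## ---- 16-risk synthetic registry ------------------------------------------

## Continuous risks: RR = exp(slope_up * (x - tmrel_hi)+ + slope_dn *
## (tmrel_lo - x)+) evaluated on the grid (then treated piecewise-linearly).
## Exposure: normal, location mean with a slow secular trend.
make_cont_risk <- function(name, applies, grid, tmrel, slope_up, slope_dn,
                           exp_mean0, exp_sd, exp_trend, rr_se, loc_shift) {
  t_lo <- min(tmrel); t_hi <- max(tmrel)
  rr <- exp(slope_up * pmax(grid - t_hi, 0) + slope_dn * pmax(t_lo - grid, 0))
  list(name = name, kind = "continuous", applies = applies,
       curve = normalize_rr(rr_curve(grid, rr), tmrel), tmrel = tmrel,
       rr_se = rr_se, exp_sd = exp_sd,
       exp_mean0 = exp_mean0, exp_trend = exp_trend, loc_shift = loc_shift)
}

make_cat_risk <- function(name, applies, categories, rr, tmrel_cat,
                          p_exposed0, p_trend, rr_se, loc_shift) {
  list(name = name, kind = "categorical", applies = applies,
       curve = normalize_rr(rr_curve(categories, rr, "categorical"),
                            tmrel_cat),
       tmrel = tmrel_cat, rr_se = rr_se,
       p_exposed0 = p_exposed0, p_trend = p_trend, loc_shift = loc_shift)
}

#' The synthetic 16-risk registry
#'
#' Sixteen diabetes risk factors with synthetic piecewise-linear RR curves,
#' TMRELs and location-year exposure parameters. High and low air
#' temperature attach to both diabetes types; all other risks attach to
#' type 2 only. Mean BMI exposure follows the world's BMI covariate; other
#' exposures get mild location shifts and secular trends.
#'
#' @param loc tibble with `location_id` (location-level shifts are derived
#'   deterministically from the id).
#' @param covariates world covariate table (`location_id`, `year`, `bmi`).
#' @param ref_year last year of the covariate series.
#' @return A named list of risk entries; see [risk_exposure] and
#'   [risk_paf_draws].
#' @export
default_risk_registry <- function(loc, covariates, ref_year) {
  L <- nrow(loc)
  shift <- function(k) sin(seq_len(L) + k) * 0.5   # deterministic, per risk
  risks <- list(
    make_cont_risk("ambient particulate matter pollution", "type2",
                   seq(0, 100, 5), c(2.4, 5.9), 0.004, 0, 35, 12, 0.1, 0.08,
                   shift(1) * 12),
    make_cat_risk("household air pollution from solid fuels", "type2",
                  c("unexposed", "exposed"), c(1, 1.25), "unexposed",
                  0.35, -0.004, 0.06, shift(2) * 0.2),
    make_cat_risk("smoking", "type2", c("never", "former", "current"),
                  c(1, 1.18, 1.45), "never", 0.28, -0.002, 0.05,
                  shift(3) * 0.1),
    make_cat_risk("second-hand smoke", "type2",
                  c("unexposed", "exposed"), c(1, 1.22), "unexposed",
                  0.30, -0.002, 0.06, shift(4) * 0.1),
    make_cat_risk("high alcohol use", "type2",
                  c("unexposed", "exposed"), c(1, 1.18), "unexposed",
                  0.12, 0.0005, 0.07, shift(5) * 0.05),
    make_cont_risk("high body-mass index", "type2",
                   seq(15, 45, 1), c(20, 25), 0.10, 0, 26, 4.2, 0.05, 0.10,
                   shift(6) * 1.5),
    make_cat_risk("diet low in fruits", "type2",
                  c("unexposed", "exposed"), c(1, 1.12), "unexposed",
                  0.45, -0.001, 0.05, shift(7) * 0.15),
    make_cat_risk("diet low in vegetables", "type2",
                  c("unexposed", "exposed"), c(1, 1.10), "unexposed",
                  0.40, -0.001, 0.05, shift(8) * 0.15),
    make_cat_risk("diet low in whole grains", "type2",
                  c("unexposed", "exposed"), c(1, 1.20), "unexposed",
                  0.55, -0.001, 0.05, shift(9) * 0.15),
    make_cat_risk("diet high in red meat", "type2",
                  c("unexposed", "exposed"), c(1, 1.15), "unexposed",
                  0.30, 0.001, 0.06, shift(10) * 0.12),
    make_cat_risk("diet high in processed meat", "type2",
                  c("unexposed", "exposed"), c(1, 1.18), "unexposed",
                  0.25, 0.001, 0.06, shift(11) * 0.12),
    make_cat_risk("diet high in sugar-sweetened beverages", "type2",
                  c("unexposed", "exposed"), c(1, 1.20), "unexposed",
                  0.30, 0.002, 0.06, shift(12) * 0.12),
    make_cat_risk("diet low in fibre", "type2",
                  c("unexposed", "exposed"), c(1, 1.12), "unexposed",
                  0.45, -0.001, 0.06, shift(13) * 0.12),
    make_cont_risk("low physical activity", "type2",
                   seq(0, 9000, 300), c(4500, 9000), 0, 1.2e-4, 3200, 1500,
                   -8, 0.08, shift(14) * 600),
    make_cont_risk("high air temperature", "both",
                   seq(-10, 40, 2), c(10, 20), 0.015, 0, 22, 5, 0.02, 0.09,
                   shift(15) * 4),
    make_cont_risk("low air temperature", "both",
                   seq(-20, 30, 2), c(12, 20), 0, 0.012, 8, 6, 0.01, 0.09,
                   shift(16) * 4)
  )
  names(risks) <- vapply(risks, `[[`, character(1), "name")
  attr(risks, "bmi_covariate") <- covariates[, c("location_id", "year",
                                                 "bmi")]
  attr(risks, "ref_year") <- ref_year
  risks
}

#' Exposure distribution of a risk for one location-year
#'
#' @param risks registry from [default_risk_registry].
#' @param name risk name.
#' @param location_id location.
#' @param year calendar year.
#' @return An [exposure_dist].
#' @export
risk_exposure <- function(risks, name, location_id, year) {
  rk <- risks[[name]]
  if (is.null(rk)) dm_abort(sprintf("unknown risk '%s'", name),
                            "dm_config_error")
  ref_year <- attr(risks, "ref_year")
  t <- year - (ref_year - 31)
  if (rk$kind == "continuous") {
    mu <- if (rk$name == "high body-mass index") {
      bmi <- attr(risks, "bmi_covariate")
      v <- bmi$bmi[bmi$location_id == location_id & bmi$year == year]
      if (length(v) == 0) rk$exp_mean0 + rk$exp_trend * t else v
    } else {
      rk$exp_mean0 + rk$loc_shift[location_id] + rk$exp_trend * t
    }
    mu <- min(max(mu, min(rk$curve$grid)), max(rk$curve$grid))
    normal_exposure(rk$curve$grid, mu, rk$exp_sd)
  } else {
    p <- min(max(rk$p_exposed0 + rk$loc_shift[location_id] +
                   rk$p_trend * t, 0.01), 0.95)
    cats <- rk$curve$grid
    probs <- setNames(rep((1 - p) / (length(cats) - 1), length(cats)), cats)
    probs[cats != rk$tmrel] <- p / (length(cats) - 1)
    probs[cats == rk$tmrel] <- 1 - p
    exposure_dist(probs, kind = "categorical")
  }
}

#' PAF draws for one risk and location-year
#'
#' RR-curve uncertainty enters as a normal draw on the log-RR scale (the
#' whole curve scaled by one factor per draw), then each drawn curve is
#' re-normalised at the TMREL and the PAF computed.
#'
#' @param risks registry; @param name risk name.
#' @param location_id,year stratum.
#' @param n draws; @param seed seed.
#' @return numeric vector of `n` PAF draws.
#' @export
risk_paf_draws <- function(risks, name, location_id, year, n = 100L,
                           seed = 1L) {
  rk <- risks[[name]]
  expo <- risk_exposure(risks, name, location_id, year)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed) + location_id * 1000L + (year %% 1000L))
  z <- rnorm(n, 0, rk$rr_se)
  vapply(z, function(zi) {
    cur <- rk$curve
    cur$rr <- exp(log(cur$rr) * exp(zi))
    cur <- normalize_rr(cur, rk$tmrel)
    compute_paf(expo, cur)
  }, numeric(1))
}
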