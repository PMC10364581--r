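## Prevalence forecasting to 2050: a single global slope on one covariate
## (SDI for type 1, mean BMI for type 2) plus a random intercept per
## location-age-sex stratum, fitted on logit prevalence; projections are
## intercept-shifted in rate space to pass exactly through the final
## estimated year, then multiplied by forecast population for case counts.

stratum_id <- function(keys) {
  paste(keys$location_id, keys$age_start, keys$sex, sep = "|")
}

LOGIT_EPS <- 1e-6

#' Fit the logit-prevalence forecasting model
#'
#' E\[logit(Y_las,y)\] = beta1 x covariate + alpha_las: one fixed slope on
#' the covariate and one intercept per location-age-sex stratum. The
#' intercepts are random (REML via lme4) by default, with a fixed-effects
#' (one dummy per stratum) variant behind `method = "fixed"`. Prevalence is
#' clamped to \[1e-6, 1 - 1e-6\] before the logit.
#'
#' @param prevalence tibble with demographic keys over years and `value` in
#'   \[0, 1\]; every stratum needs >= 3 years of history.
#' @param covariate tibble with `location_id`, `year`, `value` (the
#'   covariate is shared across age and sex within a location-year).
#' @param covariate_name "SDI" or "BMI" (recorded, not interpreted).
#' @param method "random" (default) or "fixed" intercepts.
#' @return Object of class `forecast_model`: `beta1`, `alpha` (tibble of
#'   stratum keys and intercepts), `sigma`, `covariate_name`, `method`.
#' @export
fit_forecast_model <- function(prevalence, covariate,
                               covariate_name = c("SDI", "BMI"),
                               method = c("random", "fixed")) {
  covariate_name <- match.arg(covariate_name)
  method <- match.arg(method)
  dat <- dplyr::left_join(
    prevalence,
    dplyr::rename(covariate, cov = "value"),
    by = c("location_id", "year")
  )
  if (anyNA(dat$cov)) {
    dm_abort("covariate missing for some historical location-years",
             "dm_config_error")
  }
  dat$stratum <- stratum_id(dat)
  n_per <- table(dat$stratum)
  if (any(n_per < 3)) {
    dm_abort("every stratum needs at least 3 years of history",
             "dm_config_error")
  }
  if (stats::var(dat$cov - stats::ave(dat$cov, dat$stratum)) < 1e-12) {
    dm_abort(paste0("covariate has no within-stratum variation over time; ",
                    "the slope is not identifiable"), "dm_config_error")
  }
  dat$y <- qlogis(pmin(pmax(dat$value, LOGIT_EPS), 1 - LOGIT_EPS))

  if (method == "random") {
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(y ~ cov + (1 | stratum), data = dat, REML = TRUE)))
    beta1 <- lme4::fixef(fit)[["cov"]]
    re <- lme4::ranef(fit)$stratum
    alpha <- setNames(lme4::fixef(fit)[["(Intercept)"]] + re[, 1],
                      rownames(re))
    sigma <- stats::sigma(fit)
  } else {
    fit <- lm(y ~ 0 + stratum + cov, data = dat)
    cf <- coef(fit)
    beta1 <- cf[["cov"]]
    a <- cf[grepl("^stratum", names(cf))]
    alpha <- setNames(unname(a), sub("^stratum", "", names(a)))
    sigma <- stats::sigma(fit)
  }
  strata <- dat[!duplicated(dat$stratum),
                c("location_id", "age_start", "age_end", "sex", "stratum")]
  strata$alpha <- unname(alpha[strata$stratum])
  structure(list(beta1 = beta1, alpha = tibble::as_tibble(strata),
                 sigma = sigma, covariate_name = covariate_name,
                 method = method,
                 history_years = range(dat$year)),
            class = "forecast_model")
}

#' @export
print.forecast_model <- function(x, ...) {
  cat(sprintf(
    "<forecast_model: beta1 = %.5f per unit %s, %d strata (%s intercepts)>\n",
    x$beta1, x$covariate_name, nrow(x$alpha), x$method))
  invisible(x)
}

#' Project prevalence from a fitted forecast model
#'
#' prediction = inverse-logit(beta1 x covariate + alpha) for every fitted
#' stratum and requested year.
#'
#' @param model a `forecast_model`.
#' @param covariate_forecast tibble `location_id`, `year`, `value` covering
#'   all model locations and requested years.
#' @param years years to project (default: all years in the forecast).
#' @param strata optional tibble of strata to project (must all have been
#'   seen at fit time; defaults to the model's strata).
#' @return Demographic table of projected prevalence.
#' @export
project_prevalence <- function(model, covariate_forecast,
                               years = sort(unique(covariate_forecast$year)),
                               strata = NULL) {
  if (is.null(strata)) {
    strata <- model$alpha
  } else {
    strata$stratum <- stratum_id(strata)
    unseen <- setdiff(strata$stratum, model$alpha$stratum)
    if (length(unseen) > 0) {
      dm_abort(sprintf("stratum unseen at fit time: %s", unseen[1]),
               "dm_alignment_error")
    }
    strata <- dplyr::left_join(
      strata[, c("location_id", "age_start", "age_end", "sex", "stratum")],
      model$alpha[, c("stratum", "alpha")], by = "stratum")
  }
  out <- tidyr::expand_grid(strata, year = as.integer(years)) |>
    dplyr::left_join(dplyr::rename(covariate_forecast, cov = "value"),
                     by = c("location_id", "year"))
  if (anyNA(out$cov)) {
    dm_abort("covariate forecast does not cover all strata and years",
             "dm_config_error")
  }
  out$value <- unname(plogis(model$beta1 * out$cov + out$alpha))
  out[, c(DEMO_KEYS, "value")]
}

#' Intercept-shift a projection onto the estimated anchor year
#'
#' Computes the rate-space difference between the estimate and the
#' projection at the anchor year per stratum and adds it to every projected
#' year, clamping to \[0, 1\]. The shifted projection equals the estimate
#' exactly at the anchor year.
#'
#' @param projection projected prevalence table (keys + `value`).
#' @param estimate tibble of estimated prevalence at the anchor year.
#' @param anchor_year calendar year to anchor on (default 2021).
#' @return The shifted projection; attribute `n_clamped` counts values
#'   clamped at the \[0, 1\] boundary (a warning is raised if any).
#' @export
intercept_shift <- function(projection, estimate, anchor_year = 2021L) {
  proj_anchor <- projection[projection$year == anchor_year, ]
  est <- estimate[estimate$year == anchor_year, ]
  skey <- c("location_id", "age_start", "sex")
  idx <- match(key_string(proj_anchor[skey]), key_string(est[skey]))
  if (anyNA(idx) || nrow(proj_anchor) == 0) {
    dm_abort("estimate and projection are misaligned at the anchor year",
             "dm_alignment_error")
  }
  offset <- setNames(est$value[idx] - proj_anchor$value,
                     key_string(proj_anchor[skey]))
  out <- projection
  shifted <- out$value + unname(offset[key_string(out[skey])])
  n_clamped <- sum(shifted < 0 | shifted > 1)
  if (n_clamped > 0) {
    warn(sprintf("%d shifted values clamped to [0, 1]", n_clamped),
         class = "dm_clamp_warning")
  }
  out$value <- pmin(pmax(shifted, 0), 1)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Convert a prevalence forecast to case counts
#'
#' cases = prevalence x population per cell; totals aggregate by summation.
#'
#' @param prevalence_forecast,population_forecast demographic tables on the
#'   same grid (`value` = proportion and persons respectively).
#' @return Demographic table of case counts.
#' @export
forecast_counts <- function(prevalence_forecast, population_forecast) {
  keys <- prevalence_forecast[DEMO_KEYS]
  pop <- align_table(keys, population_forecast)
  out <- prevalence_forecast
  out$value <- prevalence_forecast$value * pop
  out
}
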