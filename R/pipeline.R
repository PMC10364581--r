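## End-to-end synthetic pipeline: simulate -> crosswalk -> redistribute ->
## estimate -> burden -> attribute -> forecast, with draws carried
## throughout. This is the orchestration layer the acceptance checks run.

## Extend the covariate series through a future year by extrapolating each
## location's trend: logit-linear for SDI and obesity, BMI re-derived from
## obesity. These forecasts are inputs, not modelled quantities.
forecast_covariates <- function(world, through_year = 2050L) {
  hist <- world$covariates
  years_all <- min(hist$year):through_year
  per_loc <- function(sub) {
    fs <- lm(qlogis(sdi) ~ year, data = sub)
    fo <- lm(qlogis(obesity) ~ year, data = sub)
    tibble::tibble(
      location_id = sub$location_id[1], year = years_all,
      sdi = plogis(predict(fs, newdata = data.frame(year = years_all))),
      obesity = plogis(predict(fo, newdata = data.frame(year = years_all)))
    ) |>
      dplyr::mutate(bmi = 22.5 + 9 * .data$obesity)
  }
  hist |>
    dplyr::group_by(.data$location_id) |>
    dplyr::group_split() |>
    lapply(per_loc) |>
    dplyr::bind_rows()
}

## Population forecast: continue each location-age-sex cell's growth rate.
forecast_population <- function(world, through_year = 2050L,
                                growth = 0.01) {
  last_year <- max(world$population$year)
  base <- dplyr::filter(world$population, .data$year == last_year)
  fut <- lapply((last_year + 1):through_year, function(y) {
    dplyr::mutate(base, year = as.integer(y),
                  value = .data$value * (1 + growth)^(y - last_year))
  })
  dplyr::bind_rows(world$population, dplyr::bind_rows(fut))
}

## Fit illness-death rates for every location-sex stratum of one cause.
fit_cause_rates <- function(world, datapoints, deaths, cause, burden_year,
                            n_draws, boot_maxit = 15L, maxit = 120L,
                            smoothness = 0.05) {
  edges <- world$config$age_edges
  truth_bg <- world_truth(world, "total") |>
    dplyr::filter(.data$year == burden_year)
  pop <- dplyr::filter(world$population, .data$year == burden_year)
  strata <- tidyr::expand_grid(location_id = seq_len(world$config$n_locations),
                               sex = c("male", "female"))
  res <- lapply(seq_len(nrow(strata)), function(k) {
    l <- strata$location_id[k]; s <- strata$sex[k]
    prev <- dplyr::filter(datapoints, .data$location_id == l,
                          .data$sex == s)
    d <- dplyr::filter(deaths, .data$location_id == l, .data$sex == s,
                       .data$year == burden_year)
    p <- dplyr::filter(pop, .data$location_id == l, .data$sex == s)
    d <- d[match(edges, d$age_start), ]
    p <- p[match(edges, p$age_start), ]
    dcol <- if (cause == "type1") d$deaths_type1 else
      d$deaths_type1 + d$deaths_type2
    csmr_obs <- tibble::tibble(age_start = edges, value = dcol / p$value)
    ## all-cause mortality input minus observed diabetes csmr, floored
    tb <- dplyr::filter(truth_bg, .data$location_id == l, .data$sex == s)
    tb <- tb[match(edges, tb$age_start), ]
    all_cause <- tb$background_mort + tb$csmr
    csmr_tot <- (d$deaths_type1 + d$deaths_type2) / p$value
    m <- pmax(all_cause - csmr_tot, 1e-6)
    fit <- fit_rates(prev, csmr_obs, edges, m,
                     remission_cap = 0.01,
                     fix_remission = if (cause == "type1") 0 else NULL,
                     smoothness = smoothness, n_boot = n_draws,
                     seed = world$config$seed + 10L * l +
                       (s == "female") + ifelse(cause == "type1", 500L, 0L),
                     maxit = maxit, boot_maxit = boot_maxit)
    list(location_id = l, sex = s, fit = fit)
  })
  keys <- dplyr::bind_rows(lapply(res, function(x) {
    tibble::tibble(location_id = x$location_id,
                   age_start = edges, age_end = c(edges[-1], Inf),
                   sex = x$sex, year = as.integer(burden_year))
  }))
  prev_draws <- do.call(rbind, lapply(res, function(x) x$fit$prev_draws))
  csmr_draws <- do.call(rbind, lapply(res, function(x) x$fit$csmr_draws))
  list(prevalence = drawset(keys, prev_draws),
       csmr = drawset(keys, csmr_draws),
       fits = res)
}

#' Run the full synthetic estimation pipeline
#'
#' Generates a world, simulates noisy observations, and runs every
#' estimation stage: definition crosswalk (LTS-trimmed), unspecified-type
#' death redistribution, illness-death rate fitting with bootstrap draws,
#' type 2 by subtraction, YLL/YLD/DALY accounting with age-standardised
#' rates, risk attribution across the 16-risk registry, and prevalence
#' forecasting with intercept shift and case counts.
#'
#' @param config a [world_config].
#' @param burden_year year for the burden cross-section (default 2021).
#' @param through_year forecast horizon (default 2050).
#' @param surveys_per_stratum prevalence datapoints per location-sex for the
#'   epi fit (default 30).
#' @param survey_noise survey noise level (SE at p = 0.5; default 0.02).
#' @param outlier_rate gross-outlier rate in the crosswalk pairs.
#' @param boot_maxit optimiser cap for warm-started bootstrap refits.
#' @param verbose print stage progress.
#' @return A list with elements `world`, `ratios`, `type_split`, `deaths`,
#'   `estimates` (prevalence/csmr drawsets per cause), `burden` (yll, yld,
#'   daly, rates, age-standardised rates), `attribution` (per-risk and
#'   combined PAFs, attributable DALYs), `forecast` (prevalence and counts
#'   through `through_year` per cause), `diagnostics`.
#' @export
run_pipeline <- function(config = world_config(),
                         burden_year = 2021L, through_year = 2050L,
                         surveys_per_stratum = 30L, survey_noise = 0.02,
                         outlier_rate = 0.08, boot_maxit = 15L,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  n_draws <- config$n_draws
  say("building world")
  world <- make_world(config)
  L <- config$n_locations
  edges <- config$age_edges

  ## --- observations -------------------------------------------------------
  n_surv <- surveys_per_stratum * L * 2L
  surveys <- simulate_prevalence_surveys(
    world, definitions = names(world$def_log_ratios), noise = survey_noise,
    n = n_surv, cause = "total",
    years = (burden_year - 2):burden_year)
  surveys_t1 <- simulate_prevalence_surveys(
    world, definitions = "fpg", noise = survey_noise, n = n_surv,
    cause = "type1", years = (burden_year - 2):burden_year,
    seed = config$seed + 11L)
  ## coding quality varies by location so the training filters bite
  unspec <- plogis(qlogis(config$unspecified_death_fraction) +
                     seq(-1.2, 1.2, length.out = L))
  deaths_coded <- simulate_death_data(world, unspecified_fraction = unspec)

  ## --- crosswalk ----------------------------------------------------------
  say("crosswalk")
  pairs <- simulate_definition_pairs(world, n_pairs = 15L,
                                     outlier_rate = outlier_rate)
  ratios <- estimate_definition_ratios(pairs, trim_fraction = 0.10)
  adjusted <- adjust_datapoints(surveys, ratios)

  ## --- death redistribution ----------------------------------------------
  say("redistribution")
  obesity_cov <- world$covariates[, c("location_id", "year", "obesity")]
  training <- select_training_rows(deaths_coded, quiet = TRUE) |>
    dplyr::left_join(obesity_cov, by = c("location_id", "year"))
  type_split <- fit_type_split(training)
  deaths <- redistribute_unspecified(deaths_coded, type_split,
                                     world$covariates)

  ## --- illness-death estimation -------------------------------------------
  say("estimating total diabetes rates")
  est_total <- fit_cause_rates(world, adjusted, deaths, "total",
                               burden_year, n_draws, boot_maxit)
  say("estimating type 1 rates")
  est_type1 <- fit_cause_rates(world, surveys_t1, deaths, "type1",
                               burden_year, n_draws, boot_maxit)
  prev_type2 <- subtract_type1(est_total$prevalence, est_type1$prevalence)

  ## --- burden accounting ---------------------------------------------------
  say("burden accounting")
  pop_y <- dplyr::filter(world$population, .data$year == burden_year)
  death_cells <- dplyr::filter(deaths, .data$year == burden_year)
  mk_deaths <- function(col) {
    make_draws(death_cells[[col]], 0.05, n = n_draws,
               seed = config$seed + 20L, transform = "log",
               keys = death_cells[DEMO_KEYS])
  }
  deaths_total_ds <- mk_deaths("deaths_total")
  yll <- compute_yll(deaths_total_ds, world$life_table)
  yld <- compute_yld(est_total$prevalence, world$disability_weights, pop_y,
                     background_yld_per_capita = 0.05)
  daly <- compute_daly(yll, yld)
  std <- build_standard_population(pop_y)
  daly_rate <- rate_per_100k(daly, pop_y)
  as_daly_rate <- age_standardise(daly_rate, std)
  prev_count <- drawset(est_total$prevalence$keys,
                        est_total$prevalence$draws *
                          align_table(est_total$prevalence$keys, pop_y))
  as_prev_rate <- age_standardise(
    ds_map(est_total$prevalence, function(d) d * 100), std)

  ## --- risk attribution ----------------------------------------------------
  say("risk attribution")
  risk_names <- names(world$risks)
  paf_one_year <- function(y) {
    lapply(setNames(risk_names, risk_names), function(rn) {
      dr <- t(vapply(seq_len(L), function(l) {
        risk_paf_draws(world$risks, rn, l, y, n = n_draws,
                       seed = config$seed + 30L)
      }, numeric(n_draws)))
      drawset(tibble::tibble(location_id = seq_len(L)), dr)
    })
  }
  pafs_now <- paf_one_year(burden_year)
  pafs_then <- paf_one_year(min(config$years))
  combined_paf <- aggregate_pafs(pafs_now)
  daly_by_loc <- ds_aggregate(daly, "location_id")
  attrib <- lapply(pafs_now, function(p) attributable_burden(p, daly_by_loc))
  attrib_combined <- attributable_burden(combined_paf, daly_by_loc)
  bmi_change <- paf_percentage_change(pafs_then[["high body-mass index"]],
                                      pafs_now[["high body-mass index"]])

  ## --- forecasting ---------------------------------------------------------
  say("forecasting")
  cov_fc <- forecast_covariates(world, through_year)
  pop_fc <- forecast_population(world, through_year)
  hist_prev <- function(cause) {
    world_truth(world, cause)[, c(DEMO_KEYS, "prevalence")] |>
      dplyr::rename(value = "prevalence")
  }
  sdi_tab <- dplyr::rename(cov_fc[, c("location_id", "year", "sdi")],
                           value = "sdi")
  bmi_tab <- dplyr::rename(cov_fc[, c("location_id", "year", "bmi")],
                           value = "bmi")
  fm_t1 <- fit_forecast_model(hist_prev("type1"),
                              dplyr::filter(sdi_tab,
                                            .data$year <= burden_year),
                              "SDI")
  fm_t2 <- fit_forecast_model(hist_prev("type2"),
                              dplyr::filter(bmi_tab,
                                            .data$year <= burden_year),
                              "BMI")
  yrs_fc <- burden_year:through_year
  proj_t1 <- project_prevalence(fm_t1, sdi_tab, yrs_fc)
  proj_t2 <- project_prevalence(fm_t2, bmi_tab, yrs_fc)
  est21 <- function(ds) {
    s <- summarise_draws(ds)
    s$value <- s$mean
    s[, c(DEMO_KEYS, "value")]
  }
  shifted_t1 <- intercept_shift(proj_t1, est21(est_type1$prevalence),
                                burden_year)
  shifted_t2 <- intercept_shift(proj_t2, est21(prev_type2), burden_year)
  total_fc <- shifted_t1
  total_fc$value <- pmin(shifted_t1$value + shifted_t2$value, 1)
  counts_total <- forecast_counts(total_fc, pop_fc)
  counts_t1 <- forecast_counts(shifted_t1, pop_fc)
  counts_t2 <- forecast_counts(shifted_t2, pop_fc)

  say("done")
  list(
    world = world, surveys = adjusted, ratios = ratios,
    type_split = type_split, deaths = deaths,
    estimates = list(total = est_total, type1 = est_type1,
                     type2_prevalence = prev_type2),
    burden = list(deaths = deaths_total_ds, yll = yll, yld = yld,
                  daly = daly, daly_rate = daly_rate,
                  as_daly_rate = as_daly_rate,
                  prevalence_count = prev_count,
                  as_prev_rate = as_prev_rate,
                  standard_population = std),
    attribution = list(pafs = pafs_now, pafs_baseline = pafs_then,
                       combined_paf = combined_paf,
                       attributable_dalys = attrib,
                       attributable_combined = attrib_combined,
                       bmi_paf_change = bmi_change),
    forecast = list(model_type1 = fm_t1, model_type2 = fm_t2,
                    prevalence_type1 = shifted_t1,
                    prevalence_type2 = shifted_t2,
                    prevalence_total = total_fc,
                    counts_total = counts_total,
                    counts_type1 = counts_t1, counts_type2 = counts_t2,
                    population = pop_fc)
  )
}
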