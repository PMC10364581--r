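## Synthetic "world": a self-consistent truth (rates, prevalence, deaths,
## covariates, life table, risks) plus noisy observation simulators, so the
## whole estimation chain can be exercised and validated against a known
## answer without any external data.

#' Configuration for the synthetic world
#'
#' Defaults encode the study conditions the downstream stages assume:
#' 5-year age groups 0 to 95+, history 1990-2021, 100 draws, a majority of
#' diabetes deaths coded to unspecified type, type 2 incidence rising with
#' age and mean BMI, type 1 remission fixed at zero and total remission
#' capped at 1%/yr.
#'
#' @param n_locations number of locations (flat hierarchy plus one global
#'   aggregate downstream).
#' @param age_edges strictly increasing age-group lower edges (years).
#' @param years calendar years covered by the truth.
#' @param n_draws draw count carried end-to-end (default 100).
#' @param seed integer; a fixed seed makes the whole bundle byte-identical.
#' @param unspecified_death_fraction proportion of diabetes deaths coded to
#'   unspecified type (default 0.55: more than half).
#' @param type1_inc_peak peak type 1 incidence (per person-year, childhood).
#' @param type2_inc_scale type 2 incidence scale at BMI 25 (per person-year);
#'   set 0 to switch type 2 off entirely.
#' @param remission_type2 true type 2 remission rate (per year, < 0.01).
#' @param beta_sdi,beta_bmi true forecasting slopes: logit-prevalence units
#'   per unit SDI (type 1) and per kg/m^2 of mean BMI (type 2).
#' @param bmi_effect log-linear effect of mean BMI on type 2 incidence
#'   (per kg/m^2).
#' @param location_sd lognormal SD of location-level rate scaling.
#' @param def_log_ratios named numeric: true log-ratio of each alternate
#'   case definition to the FPG >= 7 mmol/L reference (reference must be 0).
#' @return A list of class `world_config`.
#' @export
world_config <- function(n_locations = 5L,
                         age_edges = seq(0, 95, by = 5),
                         years = 1990:2021,
                         n_draws = 100L,
                         seed = 42L,
                         unspecified_death_fraction = 0.55,
                         type1_inc_peak = 4e-4,
                         type2_inc_scale = 0.012,
                         remission_type2 = 0.004,
                         beta_sdi = 1.5,
                         beta_bmi = 0.08,
                         bmi_effect = 0.06,
                         location_sd = 0.25,
                         def_log_ratios = c(fpg = 0, hba1c = log(0.9),
                                            ogtt = log(1.15),
                                            ppg = log(1.25))) {
  cfg <- list(n_locations = as.integer(n_locations),
              age_edges = age_edges, years = as.integer(years),
              n_draws = as.integer(n_draws), seed = as.integer(seed),
              unspecified_death_fraction = unspecified_death_fraction,
              type1_inc_peak = type1_inc_peak,
              type2_inc_scale = type2_inc_scale,
              remission_type2 = remission_type2,
              beta_sdi = beta_sdi, beta_bmi = beta_bmi,
              bmi_effect = bmi_effect, location_sd = location_sd,
              def_log_ratios = def_log_ratios)
  validate_world_config(cfg)
  structure(cfg, class = "world_config")
}

#' Read a world configuration from a YAML file
#'
#' The file may set any argument of [world_config] (scalars, numeric
#' vectors, and the `def_log_ratios` named mapping); unset fields keep
#' their defaults. Unknown fields are an error, so typos do not silently
#' fall back to defaults.
#'
#' @param path path to a YAML file.
#' @return A [world_config].
#' @export
read_world_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(world_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    dm_abort(sprintf("unknown configuration field '%s'; known fields: %s",
                     bad[1], paste(known, collapse = ", ")),
             "dm_config_error")
  }
  if (!is.null(raw$def_log_ratios)) {
    raw$def_log_ratios <- unlist(raw$def_log_ratios)
  }
  do.call(world_config, raw)
}

validate_world_config <- function(cfg) {
  if (cfg$n_locations < 1) {
    dm_abort("n_locations: at least one location is required",
             "dm_config_error")
  }
  check_age_edges(cfg$age_edges)
  props <- c(unspecified_death_fraction = cfg$unspecified_death_fraction)
  bad <- props < 0 | props > 1
  if (any(bad)) {
    dm_abort(sprintf("%s must be a proportion in [0, 1]",
                     names(props)[bad][1]), "dm_config_error")
  }
  if (cfg$remission_type2 > 0.01) {
    dm_abort("remission_type2 exceeds the 1%/yr remission cap",
             "dm_config_error")
  }
  if (cfg$def_log_ratios[["fpg"]] != 0) {
    dm_abort("reference definition 'fpg' must have log-ratio 0",
             "dm_config_error")
  }
  invisible(cfg)
}

## Smooth truth curves. Type 2 incidence is zero below age 15 (all childhood
## diabetes is type 1) and scales log-linearly with mean BMI.
true_incidence_type1 <- function(a, scale) {
  scale * exp(-((a - 12) / 16)^2)
}
true_incidence_type2 <- function(a, scale, bmi, bmi_effect) {
  ifelse(a < 15, 0, scale * plogis((a - 45) / 12) *
           exp(bmi_effect * (bmi - 25)))
}
true_excess_mort <- function(a, scale) scale * (0.01 + 3e-4 * a)
true_background_mort <- function(a) pmin(8e-4 * exp(0.073 * a), 0.7)

#' Generate the synthetic world
#'
#' Builds population, true illness-death rates per diabetes type (type 1 +
#' type 2 summing to total; per-type prevalence is the exact illness-death
#' solution of the per-type rates), covariate series (SDI, obesity
#' prevalence, mean BMI), a standard life table, disability weights and
#' sequela splits, and the 16-risk comparative-risk-assessment registry.
#' Deterministic given `config$seed`.
#'
#' @param config a [world_config].
#' @return A list of class `world_bundle` with elements `config`,
#'   `population`, `rates`, `covariates`, `life_table`,
#'   `disability_weights`, `risks`, `def_log_ratios`.
#' @export
make_world <- function(config = world_config()) {
  validate_world_config(config)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed)

  L <- config$n_locations
  edges <- config$age_edges
  G <- length(edges)
  mids <- age_midpoint(edges, c(edges[-1], Inf))
  years <- config$years
  sexes <- c("male", "female")

  ## location-level heterogeneity
  loc <- tibble::tibble(
    location_id = seq_len(L),
    base_pop = exp(runif(L, log(2e6), log(4e7))),
    scale_t1 = exp(rnorm(L, 0, config$location_sd)),
    scale_t2 = exp(rnorm(L, 0, config$location_sd)),
    scale_f = exp(rnorm(L, 0, config$location_sd / 2)),
    sdi0 = runif(L, 0.3, 0.8),
    ob0 = runif(L, 0.1, 0.35)
  )

  ## covariates drift upward over time; BMI tracks obesity
  covariates <- tidyr::expand_grid(location_id = seq_len(L), year = years) |>
    dplyr::left_join(loc, by = "location_id") |>
    dplyr::mutate(
      t = .data$year - min(years),
      sdi = plogis(qlogis(.data$sdi0) + 0.015 * .data$t),
      obesity = plogis(qlogis(.data$ob0) + 0.02 * .data$t),
      bmi = 22.5 + 9 * .data$obesity
    ) |>
    dplyr::select("location_id", "year", "sdi", "obesity", "bmi")

  ## population: declining age structure, mild growth
  age_w <- exp(-0.032 * mids)
  population <- demographic_grid(seq_len(L), edges, sexes, years) |>
    dplyr::left_join(loc[, c("location_id", "base_pop")],
                     by = "location_id") |>
    dplyr::mutate(
      value = .data$base_pop *
        age_w[match(.data$age_start, edges)] / sum(age_w) / 2 *
        1.01^(.data$year - min(years))
    ) |>
    dplyr::select(dplyr::all_of(DEMO_KEYS), "value")

  ## true rates and their exact illness-death solutions, per stratum-year
  sex_mult <- c(male = 1.08, female = 0.92)
  strata <- tidyr::expand_grid(location_id = seq_len(L), sex = sexes,
                               year = years) |>
    dplyr::left_join(loc, by = "location_id") |>
    dplyr::left_join(covariates, by = c("location_id", "year"))

  one_stratum <- function(k) {
    s <- strata[k, ]
    i1 <- true_incidence_type1(mids, config$type1_inc_peak * s$scale_t1) *
      sex_mult[[s$sex]]
    i2 <- true_incidence_type2(mids, config$type2_inc_scale * s$scale_t2,
                               s$bmi, config$bmi_effect) * sex_mult[[s$sex]]
    f1 <- true_excess_mort(mids, 2.2 * s$scale_f)
    f2 <- true_excess_mort(mids, 1.0 * s$scale_f)
    m <- true_background_mort(mids)
    r1 <- rep(0, G)
    r2 <- rep(config$remission_type2, G)
    b1 <- solve_illness_death(i1, r1, f1, m, edges)
    b2 <- solve_illness_death(i2, r2, f2, m, edges)
    tot <- tibble::tibble(
      age_start = b1$age_start, age_end = b1$age_end,
      incidence = i1 + i2, remission = r1 + r2,
      excess_mort = f1 + f2, background_mort = m,
      prevalence = b1$prevalence + b2$prevalence,
      csmr = b1$csmr + b2$csmr
    )
    dplyr::bind_rows(
      dplyr::mutate(tibble::as_tibble(b1), cause = "type1"),
      dplyr::mutate(tibble::as_tibble(b2), cause = "type2"),
      dplyr::mutate(tot, cause = "total")
    ) |>
      dplyr::mutate(location_id = s$location_id, sex = s$sex,
                    year = s$year)
  }
  rates <- dplyr::bind_rows(lapply(seq_len(nrow(strata)), one_stratum)) |>
    dplyr::select("location_id", "sex", "year", "cause",
                  "age_start", "age_end", dplyr::everything())

  life_table <- tibble::tibble(
    age_start = edges, age_end = c(edges[-1], Inf),
    life_exp = pmax(88 - 0.92 * mids, 2)
  )

  disability_weights <- tibble::tibble(
    sequela = c("neuropathy", "diabetic foot", "lower limb amputation",
                "vision loss due to retinopathy"),
    dw = c(0.133, 0.165, 0.164, 0.184),
    split = c(0.25, 0.06, 0.02, 0.04)
  )

  risks <- default_risk_registry(loc, covariates, max(years))

  structure(list(config = config, population = population, rates = rates,
                 covariates = covariates, life_table = life_table,
                 disability_weights = disability_weights, risks = risks,
                 def_log_ratios = config$def_log_ratios),
            class = "world_bundle")
}

#' @export
print.world_bundle <- function(x, ...) {
  cat(sprintf(
    "<world_bundle: %d locations, %d age groups, years %d-%d, %d draws>\n",
    x$config$n_locations, length(x$config$age_edges),
    min(x$config$years), max(x$config$years), x$config$n_draws))
  invisible(x)
}

## Look up true prevalence/csmr for given cells.
world_truth <- function(world, cause = "total") {
  dplyr::filter(world$rates, .data$cause == !!cause)
}

#' Simulate prevalence survey datapoints
#'
#' Draws survey-style prevalence observations from the world's truth under a
#' chosen case definition. Non-reference definitions are biased by their
#' known log-ratio (observed expectation = truth x exp(log-ratio), capped at
#' 1). The noise model is binomial sampling at an effective sample size
#' `0.25/noise^2` (so `noise` is the standard error at prevalence 0.5), with
#' the binomial standard error reported; `noise = 0` returns the expectation
#' exactly. A fraction of datapoints are gross outliers: truth multiplied by
#' a factor drawn from \{0.2, 5\}.
#'
#' @param world a `world_bundle`.
#' @param definitions character vector of case-definition labels.
#' @param noise positive real noise level (SE at p = 0.5); 0 for noiseless.
#' @param n number of datapoints to simulate.
#' @param outlier_rate proportion of gross outliers (default 0).
#' @param cause truth layer sampled ("total" or "type1").
#' @param years optional subset of years to sample from.
#' @param seed seed (default derived from the world seed).
#' @return A tibble: demographic keys, `definition`, `value`, `se`, and the
#'   truth-side diagnostics `truth` and `true_outlier`.
#' @export
simulate_prevalence_surveys <- function(world, definitions = "fpg",
                                        noise = 0.02, n = 200L,
                                        outlier_rate = 0, cause = "total",
                                        years = NULL, seed = NULL) {
  known <- names(world$def_log_ratios)
  bad <- setdiff(definitions, known)
  if (length(bad) > 0) {
    dm_abort(sprintf("unknown case definition '%s'; known: %s", bad[1],
                     paste(known, collapse = ", ")), "dm_config_error")
  }
  if (noise < 0) dm_abort("noise must be non-negative", "dm_config_error")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(if (is.null(seed)) world$config$seed + 1L else as.integer(seed))

  truth <- world_truth(world, cause)
  if (!is.null(years)) truth <- dplyr::filter(truth, .data$year %in% !!years)
  rows <- truth[sample.int(nrow(truth), n, replace = TRUE), ]
  def <- sample(definitions, n, replace = TRUE)
  lr <- unname(world$def_log_ratios[def])
  is_out <- runif(n) < outlier_rate
  out_fac <- ifelse(runif(n) < 0.5, 0.2, 5)
  expect <- pmin(rows$prevalence * exp(lr) * ifelse(is_out, out_fac, 1), 1)

  if (noise == 0) {
    value <- expect
    se <- rep(0, n)
  } else {
    ess <- max(10, round(0.25 / noise^2))
    k <- rbinom(n, ess, expect)
    value <- k / ess
    se <- sqrt(pmax(value * (1 - value), 1 / ess) / ess)
  }
  tibble::tibble(
    location_id = rows$location_id, age_start = rows$age_start,
    age_end = rows$age_end, sex = rows$sex, year = rows$year,
    definition = def, value = value, se = se,
    truth = rows$prevalence, true_outlier = is_out
  )
}

#' Simulate matched reference/alternate definition pairs
#'
#' Draws cells from the world truth and observes each under both the
#' reference definition and one alternate, with independent multiplicative
#' lognormal noise; optionally contaminates a fraction of pairs with gross
#' outliers (alternate multiplied by 0.2 or 5). Input for
#' [estimate_definition_ratios].
#'
#' @param world a `world_bundle`.
#' @param definitions alternate definitions to pair against the reference.
#' @param n_pairs pairs per definition.
#' @param noise_sd lognormal (log-scale) observation noise SD.
#' @param outlier_rate proportion of contaminated pairs.
#' @param seed seed (default derived from the world seed).
#' @return tibble `definition`, `ref_value`, `alt_value`, `true_outlier`.
#' @export
simulate_definition_pairs <- function(world,
                                      definitions = setdiff(
                                        names(world$def_log_ratios), "fpg"),
                                      n_pairs = 20L, noise_sd = 0.05,
                                      outlier_rate = 0, seed = NULL) {
  known <- names(world$def_log_ratios)
  bad <- setdiff(definitions, known)
  if (length(bad) > 0) {
    dm_abort(sprintf("unknown case definition '%s'; known: %s", bad[1],
                     paste(known, collapse = ", ")), "dm_config_error")
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(if (is.null(seed)) world$config$seed + 3L else as.integer(seed))
  truth <- dplyr::filter(world_truth(world, "total"), .data$prevalence > 1e-4)
  out <- lapply(definitions, function(d) {
    rows <- truth[sample.int(nrow(truth), n_pairs, replace = TRUE), ]
    lr <- world$def_log_ratios[[d]]
    is_out <- runif(n_pairs) < outlier_rate
    fac <- ifelse(runif(n_pairs) < 0.5, 0.2, 5)
    tibble::tibble(
      definition = d,
      ref_value = rows$prevalence * exp(rnorm(n_pairs, 0, noise_sd)),
      alt_value = rows$prevalence * exp(lr) *
        exp(rnorm(n_pairs, 0, noise_sd)) * ifelse(is_out, fac, 1),
      true_outlier = is_out
    )
  })
  dplyr::bind_rows(out)
}

#' Simulate deaths by coded diabetes type
#'
#' Computes true diabetes deaths per demographic cell (population x CSMR),
#' then codes a fixed fraction to "unspecified" type. Among coded deaths the
#' type split follows the world's true type-specific CSMR ratio with mild
#' logit-normal coding noise; deaths under age 15 are all truly type 1.
#' Total deaths are conserved exactly in every cell.
#'
#' @param world a `world_bundle`.
#' @param unspecified_fraction proportion of deaths coded to unspecified
#'   type, in \[0, 1\]; a scalar, or one value per location to emulate
#'   between-country differences in coding quality (default: the world
#'   config value).
#' @param coding_sd logit-scale SD of the coding noise on the cell-level
#'   type 2 share (default 0.15).
#' @param seed seed (default derived from the world seed).
#' @return A tibble keyed by cell with columns `deaths_type1`,
#'   `deaths_type2`, `deaths_unspecified`, `deaths_total`, and the truth
#'   column `true_type2_share`.
#' @export
simulate_death_data <- function(world,
                                unspecified_fraction =
                                  world$config$unspecified_death_fraction,
                                coding_sd = 0.15, seed = NULL) {
  if (any(unspecified_fraction < 0 | unspecified_fraction > 1)) {
    dm_abort("unspecified_fraction must be in [0, 1]", "dm_config_error")
  }
  L <- world$config$n_locations
  if (!length(unspecified_fraction) %in% c(1L, L)) {
    dm_abort("unspecified_fraction must be a scalar or one value per location",
             "dm_config_error")
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(if (is.null(seed)) world$config$seed + 2L else as.integer(seed))

  csmr <- world$rates |>
    dplyr::filter(.data$cause %in% c("type1", "type2")) |>
    dplyr::select(dplyr::all_of(DEMO_KEYS), "cause", "csmr") |>
    tidyr::pivot_wider(names_from = "cause", values_from = "csmr")
  tab <- dplyr::inner_join(world$population, csmr, by = DEMO_KEYS) |>
    dplyr::mutate(
      deaths_total = .data$value * (.data$type1 + .data$type2),
      true_share = ifelse(.data$age_start < 15, 0,
                          ifelse(.data$type1 + .data$type2 > 0,
                                 .data$type2 / (.data$type1 + .data$type2),
                                 0))
    )
  n <- nrow(tab)
  frac <- if (length(unspecified_fraction) == 1L) {
    rep(unspecified_fraction, n)
  } else unspecified_fraction[tab$location_id]
  share <- ifelse(
    tab$true_share %in% c(0, 1), tab$true_share,
    plogis(qlogis(tab$true_share) + rnorm(n, 0, coding_sd)))
  coded <- tab$deaths_total * (1 - frac)
  tibble::tibble(
    tab[DEMO_KEYS],
    deaths_type1 = coded * (1 - share),
    deaths_type2 = coded * share,
    deaths_unspecified = tab$deaths_total * frac,
    deaths_total = tab$deaths_total,
    true_type2_share = tab$true_share
  )
}
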