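## simulate logit-prevalence panels with known slope and intercepts
sim_panel <- function(beta1 = 0.08, n_strata = 30, years = 1990:2021,
                      resid_sd = 0, seed = 1) {
  set.seed(seed)
  strata <- tibble::tibble(
    location_id = rep(1:5, length.out = n_strata),
    age_start = 5 * (seq_len(n_strata) %% 12) + 20,
    sex = rep(c("male", "female"), length.out = n_strata)
  ) |>
    dplyr::distinct() |>
    dplyr::mutate(age_end = age_start + 5,
                  alpha = rnorm(dplyr::n(), -3, 0.6))
  cov <- tidyr::expand_grid(location_id = unique(strata$location_id),
                            year = years) |>
    dplyr::mutate(value = 24 + 0.08 * (year - min(year)) +
                    0.3 * location_id)
  dat <- tidyr::expand_grid(strata, year = years) |>
    dplyr::left_join(cov, by = c("location_id", "year")) |>
    dplyr::mutate(value = plogis(beta1 * value + alpha +
                                   rnorm(dplyr::n(), 0, resid_sd)))
  list(prev = dat[, c("location_id", "age_start", "age_end", "sex",
                      "year", "value")],
       cov = cov, strata = strata)
}

test_that("a noiseless slope is recovered to machine precision", {
  px <- sim_panel(beta1 = 0.08, resid_sd = 0)
  m <- fit_forecast_model(px$prev, px$cov, "BMI", method = "fixed")
  expect_equal(m$beta1, 0.08, tolerance = 1e-6)
  ## random-intercept variant agrees closely in the noiseless limit
  mr <- fit_forecast_model(px$prev, px$cov, "BMI", method = "random")
  expect_equal(mr$beta1, 0.08, tolerance = 1e-4)
})

test_that("the slope is recovered within 10% under noise (median of seeds)", {
  errs <- vapply(1:50, function(s) {
    px <- sim_panel(beta1 = 0.08, n_strata = 30, resid_sd = 0.05, seed = s)
    m <- fit_forecast_model(px$prev, px$cov, "BMI")
    abs(m$beta1 - 0.08) / 0.08
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("degenerate designs are rejected", {
  px <- sim_panel()
  flat <- dplyr::mutate(px$cov, value = 25)
  expect_error(fit_forecast_model(px$prev, flat, "BMI"),
               "not identifiable", class = "dm_config_error")
  short <- dplyr::filter(px$prev, year <= 1991)
  expect_error(fit_forecast_model(short, px$cov, "BMI"),
               "3 years", class = "dm_config_error")
  expect_error(fit_forecast_model(px$prev, px$cov[0, ], "BMI"),
               class = "dm_config_error")
})

test_that("projection inverts the logit and respects monotonicity", {
  px <- sim_panel(beta1 = 0.1, resid_sd = 0)
  m <- fit_forecast_model(px$prev, px$cov, "BMI", method = "fixed")
  fut <- tidyr::expand_grid(location_id = unique(px$cov$location_id),
                            year = 2022:2050) |>
    dplyr::mutate(value = 27 + 0.1 * (year - 2022) + 0.3 * location_id)
  proj <- project_prevalence(m, fut)
  ## rising covariate with positive slope: projection rises per stratum
  one <- dplyr::filter(proj, location_id == 1,
                       age_start == proj$age_start[1],
                       sex == proj$sex[1]) |> dplyr::arrange(year)
  expect_true(all(diff(one$value) > 0))
  ## constant covariate: flat projection
  flat_fut <- dplyr::mutate(fut, value = 26)
  pf <- project_prevalence(m, flat_fut)
  expect_equal(length(unique(round(
    pf$value[pf$location_id == 1 & pf$age_start == pf$age_start[1] &
               pf$sex == pf$sex[1]], 12))), 1)
  ## unseen stratum errors by name
  ghost <- tibble::tibble(location_id = 99L, age_start = 20,
                          age_end = 25, sex = "male")
  expect_error(project_prevalence(m, fut, strata = ghost), "99",
               class = "dm_alignment_error")
})

test_that("logit(0) inputs survive via boundary clamping", {
  px <- sim_panel(resid_sd = 0)
  prev0 <- px$prev
  prev0$value[1] <- 0
  expect_silent(m <- fit_forecast_model(prev0, px$cov, "BMI",
                                        method = "fixed"))
  expect_true(is.finite(m$beta1))
})

test_that("intercept shift anchors the projection exactly", {
  px <- sim_panel(resid_sd = 0)
  m <- fit_forecast_model(px$prev, px$cov, "BMI", method = "fixed")
  fut <- tidyr::expand_grid(location_id = unique(px$cov$location_id),
                            year = 2021:2050) |>
    dplyr::mutate(value = 26 + 0.1 * (year - 2021) + 0.3 * location_id)
  proj <- project_prevalence(m, fut)
  est <- dplyr::filter(px$prev, year == 2021) |>
    dplyr::mutate(value = value + 0.02)
  shifted <- intercept_shift(proj, est, 2021L)
  at21 <- dplyr::inner_join(
    dplyr::filter(shifted, year == 2021), est,
    by = c("location_id", "age_start", "sex"))
  expect_equal(at21$value.x, at21$value.y, tolerance = 1e-12)
  ## a projection already matching the estimate is unchanged
  same <- intercept_shift(proj, dplyr::filter(proj, year == 2021), 2021L)
  expect_equal(same$value, proj$value, tolerance = 1e-12)
  ## shifts above 1 clamp with a warning
  est_hi <- dplyr::mutate(est, value = 0.999)
  expect_warning(hi <- intercept_shift(proj, est_hi, 2021L),
                 class = "dm_clamp_warning")
  expect_true(all(hi$value <= 1))
})

test_that("case counts multiply prevalence and population", {
  prev <- tibble::tibble(location_id = 1L, age_start = 20, age_end = 25,
                         sex = "male", year = 2030L, value = 0.10)
  pop <- dplyr::mutate(prev, value = 1e6)
  expect_equal(forecast_counts(prev, pop)$value, 1e5)
  pop0 <- dplyr::mutate(prev, value = 0)
  expect_equal(forecast_counts(prev, pop0)$value, 0)
  expect_error(forecast_counts(prev, dplyr::mutate(pop, year = 2031L)),
               class = "dm_alignment_error")
})
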