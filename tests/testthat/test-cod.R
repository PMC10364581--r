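## hand-built country-year death tables for the filter logic
cy_table <- function(location_id, year, t1, t2, unspec, age_start = 60) {
  tibble::tibble(location_id = location_id, year = year,
                 age_start = age_start, age_end = age_start + 5,
                 sex = "male", deaths_type1 = t1, deaths_type2 = t2,
                 deaths_unspecified = unspec)
}

test_that("training filters retain exactly the qualifying country-years", {
  tab <- dplyr::bind_rows(
    cy_table(1, 2000, t1 = 10, t2 = 70, unspec = 20),   # 80% coded, 87% t2
    cy_table(2, 2000, t1 = 10, t2 = 30, unspec = 60),   # 40% coded -> out
    cy_table(3, 2000, t1 = 32, t2 = 48, unspec = 20),   # 60% t2 -> out
    cy_table(4, 2000, t1 = 20, t2 = 75, unspec = 5)     # 95% coded, 79% t2
  )
  kept <- suppressMessages(select_training_rows(tab))
  expect_setequal(kept$location_id, c(1, 4))
  excl <- attr(kept, "excluded")
  expect_equal(sort(excl$location_id), c(2, 3))
  expect_match(excl$filter[excl$location_id == 2], "coded fraction")
  expect_match(excl$filter[excl$location_id == 3], "type-2 share")
  ## messages name the failing filter
  expect_message(select_training_rows(tab), "coded fraction")
})

test_that("filters are evaluated at the stated boundaries", {
  ## exactly 50% coded fails the strict > filter
  at_half <- cy_table(1, 2000, t1 = 5, t2 = 45, unspec = 50)
  kept <- suppressMessages(select_training_rows(at_half))
  expect_equal(nrow(kept), 0)
  ## exactly 70% type-2 share passes the >= filter
  at_70 <- cy_table(1, 2000, t1 = 30, t2 = 70, unspec = 0)
  expect_equal(nrow(suppressMessages(select_training_rows(at_70))), 1)
  expect_error(select_training_rows(dplyr::select(at_70, -age_start)),
               class = "dm_schema_error")
})

sim_training <- function(n = 60, b_obesity = 0, base_share = 0.6,
                         noise = 0.1, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    location_id = rep(1:6, length.out = n),
    year = 2000 + seq_len(n) %% 10,
    age_start = sample(seq(25, 80, 5), n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    obesity = runif(n, 0.05, 0.5)
  ) |>
    dplyr::mutate(
      age_end = age_start + 5,
      share = pmin(base_share * exp(b_obesity * obesity +
                                      rnorm(n, 0, noise)), 0.99),
      deaths_type1 = 100 * (1 - share),
      deaths_type2 = 100 * share,
      deaths_unspecified = 50
    )
}

test_that("a constant type-2 share is recovered by the intercept", {
  tab <- sim_training(n = 40, base_share = 0.9, noise = 0)
  m <- fit_type_split(tab)
  pred <- predict_type2_share(m, tab)
  expect_equal(pred, rep(0.9, nrow(tab)), tolerance = 1e-6)
})

test_that("too few rows and collinear designs are rejected", {
  tab <- sim_training(n = 40)
  expect_error(fit_type_split(tab[1:6, ]), "at least 10",
               class = "dm_config_error")
  tab$obesity <- tab$age_start / 100   # exact collinearity with age
  expect_error(fit_type_split(tab), "collinear", class = "dm_fit_error")
  expect_error(fit_type_split(dplyr::select(sim_training(), -obesity)),
               class = "dm_schema_error")
})

test_that("obesity CI covers zero when the truth has no obesity effect", {
  hits <- vapply(1:200, function(s) {
    tab <- sim_training(n = 40, b_obesity = 0, noise = 0.15, seed = s)
    m <- fit_type_split(tab)
    m$obesity_ci[1] <= 0 && 0 <= m$obesity_ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("redistribution conserves totals and applies the under-15 rule", {
  w <- tiny_world()
  deaths <- simulate_death_data(w, unspecified_fraction = 0.5)
  training <- suppressMessages(
    select_training_rows(simulate_death_data(w, unspecified_fraction = 0.2))
  ) |>
    dplyr::left_join(w$covariates[, c("location_id", "year", "obesity")],
                     by = c("location_id", "year"))
  m <- fit_type_split(training)
  out <- redistribute_unspecified(deaths, m, w$covariates)
  expect_equal(out$deaths_type1 + out$deaths_type2, deaths$deaths_total,
               tolerance = 1e-12)
  expect_true(all(out$deaths_type2[out$age_start < 15] == 0))
})

test_that("a known proportional split is applied to unspecified deaths", {
  ## age 60-64 cell, 100 unspecified, predicted share ~0.9
  tab <- sim_training(n = 40, base_share = 0.9, noise = 0)
  m <- fit_type_split(tab)
  cells <- tibble::tibble(location_id = 1L, year = 2000L, age_start = 60,
                          age_end = 65, sex = "male", deaths_type1 = 0,
                          deaths_type2 = 0, deaths_unspecified = 100)
  cov <- tibble::tibble(location_id = 1L, year = 2000L, obesity = 0.2)
  out <- redistribute_unspecified(cells, m, cov)
  expect_equal(out$deaths_type2, 90, tolerance = 1e-4)
  expect_equal(out$deaths_type1, 10, tolerance = 1e-4)
  ## age 10-14: everything to type 1
  cells$age_start <- 10; cells$age_end <- 15
  out2 <- redistribute_unspecified(cells, m, cov)
  expect_equal(out2$deaths_type1, 100)
  expect_equal(out2$deaths_type2, 0)
})

test_that("hidden type splits are recovered within 2 percentage points", {
  w <- tiny_world()
  ## well-coded table to train on; poorly-coded table to redistribute
  train_tab <- suppressMessages(
    select_training_rows(simulate_death_data(w, unspecified_fraction = 0.1,
                                             seed = 5))
  ) |>
    dplyr::left_join(w$covariates[, c("location_id", "year", "obesity")],
                     by = c("location_id", "year"))
  m <- fit_type_split(train_tab)
  hidden <- simulate_death_data(w, unspecified_fraction = 0.8, seed = 6)
  out <- redistribute_unspecified(hidden, m, w$covariates)
  est_share <- sum(out$deaths_type2) / sum(out$deaths_total)
  true_share <- sum(hidden$true_type2_share * hidden$deaths_total) /
    sum(hidden$deaths_total)
  expect_lt(abs(est_share - true_share), 0.02)
})
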