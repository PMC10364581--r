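cell_keys <- function(n, age_start = seq(50, length.out = n, by = 5)) {
  tibble::tibble(location_id = 1L, age_start = age_start,
                 age_end = age_start + 5, sex = "male", year = 2021L)
}

test_that("YLLs are deaths times remaining life expectancy", {
  lt <- tibble::tibble(age_start = c(50, 55), life_exp = c(30, 20))
  deaths <- drawset(cell_keys(2), matrix(c(1, 0), 2, 3))
  yll <- compute_yll(deaths, lt)
  expect_equal(yll$draws[1, ], rep(30, 3))
  expect_equal(yll$draws[2, ], rep(0, 3))
  deaths2 <- drawset(cell_keys(2), matrix(c(10, 5), 2, 3))
  lt2 <- tibble::tibble(age_start = c(50, 55), life_exp = c(40, 20))
  expect_equal(colSums(compute_yll(deaths2, lt2)$draws), rep(500, 3))
  expect_error(compute_yll(drawset(cell_keys(1, 95), matrix(1)), lt),
               class = "dm_config_error")
})

test_that("multiplicative comorbidity combination allocates by DW share", {
  ## two conditions with DWs 0.2 and 0.3: combined 1 - 0.8*0.7 = 0.44,
  ## share of the first = 0.44 * 0.2/0.5 = 0.176
  expect_equal(dmburden:::comorbidity_corrected_dw(0.2, 0.3),
               0.44 * 0.2 / 0.5)
  expect_equal(dmburden:::comorbidity_corrected_dw(0.2, 0), 0.2)
})

test_that("YLDs follow prevalence x split x DW with comorbidity correction", {
  keys <- cell_keys(1)
  pop <- dplyr::mutate(keys, value = 1000)
  prev <- drawset(keys, matrix(0.1, 1, 3))
  seq1 <- tibble::tibble(sequela = "neuropathy", dw = 0.2, split = 1)
  ## no comorbidity: 0.1 * 1000 * 0.2 = 20
  yld <- compute_yld(prev, seq1, pop, background_yld_per_capita = 0)
  expect_equal(yld$draws[1, ], rep(20, 3))
  ## background disability shrinks but never increases YLD
  yld_b <- compute_yld(prev, seq1, pop, background_yld_per_capita = 0.1)
  expect_true(all(yld_b$draws < yld$draws))
  expect_error(compute_yld(prev, tibble::tibble(sequela = "x", dw = 1.2,
                                                split = 1), pop),
               class = "dm_config_error")
  expect_error(compute_yld(prev, tibble::tibble(sequela = c("a", "b"),
                                                dw = c(0.2, 0.3),
                                                split = c(0.6, 0.6)), pop),
               class = "dm_config_error")
})

test_that("DALY = YLL + YLD per draw, per cell, and after aggregation", {
  set.seed(55)
  keys <- tidyr::expand_grid(location_id = 1:3,
                             age_start = seq(40, 60, 5)) |>
    dplyr::mutate(age_end = age_start + 5, sex = "female", year = 2021L)
  n <- nrow(keys)
  yll <- drawset(keys, matrix(runif(n * 10, 0, 100), n))
  yld <- drawset(keys, matrix(runif(n * 10, 0, 100), n))
  daly <- compute_daly(yll, yld)
  expect_equal(daly$draws, yll$draws + yld$draws)
  agg <- ds_aggregate(daly, "location_id")
  agg_sum <- ds_aggregate(yll, "location_id")$draws +
    ds_aggregate(yld, "location_id")$draws
  expect_equal(agg$draws, agg_sum, tolerance = 1e-9)
  ## misaligned draw counts fail loudly
  expect_error(compute_daly(yll, drawset(keys, matrix(1, n, 5))),
               class = "dm_alignment_error")
})

test_that("standard population averages qualifying age distributions", {
  pop <- tibble::tibble(
    location_id = rep(1:3, each = 2),
    age_start = rep(c(0, 50), 3), age_end = rep(c(50, Inf), 3),
    sex = "both", year = 2019L,
    value = c(6e6, 4e6,       # loc 1: (0.6, 0.4), total 10M
              2e6, 8e6,       # loc 2: (0.2, 0.8), total 10M
              2e6, 2.999999e6)  # loc 3: total 4 999 999 -> excluded
  )
  std <- build_standard_population(pop)
  expect_equal(std$weight[std$age_start == 0], 0.4)
  expect_equal(std$weight[std$age_start == 50], 0.6)
  expect_equal(sum(std$weight), 1, tolerance = 1e-12)
  ## single qualifying location: standard equals its own distribution
  std1 <- build_standard_population(pop[pop$location_id == 1, ])
  expect_equal(std1$weight, c(0.6, 0.4))
  expect_error(build_standard_population(pop[pop$location_id == 3, ]),
               class = "dm_config_error")
})

test_that("age-standardisation is a weighted mean within the rate range", {
  keys <- cell_keys(2, c(50, 55))
  std <- tibble::tibble(age_start = c(50, 55), weight = c(0.5, 0.5))
  rates <- drawset(keys, matrix(c(100, 300), 2, 4))
  as_rate <- age_standardise(rates, std)
  expect_equal(as_rate$draws[1, ], rep(200, 4))
  ## identical rates across ages pass through
  flat <- drawset(keys, matrix(150, 2, 4))
  expect_equal(age_standardise(flat, std)$draws[1, ], rep(150, 4))
  ## order invariance
  perm <- drawset(keys[2:1, ], rates$draws[2:1, , drop = FALSE])
  expect_equal(age_standardise(perm, std)$draws, as_rate$draws)
  ## bounds on random cases
  set.seed(77)
  for (k in 1:10) {
    r <- drawset(keys, matrix(runif(8, 0, 1000), 2))
    w <- runif(2); std_k <- tibble::tibble(age_start = c(50, 55),
                                           weight = w / sum(w))
    as_k <- age_standardise(r, std_k)$draws
    expect_true(all(as_k >= apply(r$draws, 2, min) - 1e-9 &
                      as_k <= apply(r$draws, 2, max) + 1e-9))
  }
})

test_that("rates per 100k scale inversely with population", {
  keys <- cell_keys(1)
  pop1 <- dplyr::mutate(keys, value = 1e6)
  pop2 <- dplyr::mutate(keys, value = 2e6)
  counts <- drawset(keys, matrix(50, 1, 3))
  expect_equal(rate_per_100k(counts, pop1)$draws[1, ], rep(5, 3))
  expect_equal(rate_per_100k(counts, pop2)$draws[1, ], rep(2.5, 3))
  expect_equal(rate_per_100k(drawset(keys, matrix(0, 1, 3)),
                             pop1)$draws[1, ], rep(0, 3))
  expect_error(rate_per_100k(counts, dplyr::mutate(keys, value = 0)),
               class = "dm_domain_error")
})
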