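test_that("normalisation divides by the RR at the TMREL", {
  ## linear RR from 1 at x=20 to 3 at x=40: interpolant at 30 is 2
  cur <- rr_curve(c(20, 40), c(1, 3))
  norm <- normalize_rr(cur, 30)
  expect_equal(norm$rr, c(1, 3) / 2)
  ## constant curve becomes constant 1
  flat <- normalize_rr(rr_curve(c(0, 10), c(3, 3)), 5)
  expect_equal(flat$rr, c(1, 1))
  ## already normalised curve is unchanged
  cur2 <- normalize_rr(rr_curve(c(20, 40), c(1, 3)), 20)
  expect_equal(cur2$rr, c(1, 3))
  ## interval TMREL divides by the mean RR over the interval
  cur3 <- normalize_rr(rr_curve(c(20, 40), c(1, 3)), c(20, 40))
  expect_equal(dmburden:::rr_at_tmrel(cur3), 1, tolerance = 1e-12)
  expect_error(normalize_rr(rr_curve(c(20, 40), c(1, 3)), 50),
               class = "dm_config_error")
})

test_that("categorical PAFs match the closed form", {
  ## binary exposure: 30% at RR 2 -> PAF = 0.3/1.3
  cur <- normalize_rr(rr_curve(c("ref", "exp"), c(1, 2), "categorical"),
                      "ref")
  expo <- exposure_dist(c(ref = 0.7, exp = 0.3), kind = "categorical")
  expect_equal(compute_paf(expo, cur), 0.3 / 1.3, tolerance = 1e-12)
  ## three categories
  cur3 <- normalize_rr(rr_curve(c("a", "b", "c"), c(1, 1.5, 2.5),
                                "categorical"), "a")
  expo3 <- exposure_dist(c(a = 0.5, b = 0.3, c = 0.2), kind = "categorical")
  expect_equal(compute_paf(expo3, cur3), 0.45 / 1.45, tolerance = 1e-12)
  ## whole population at TMREL: PAF = 0
  expect_equal(compute_paf(exposure_dist(c(ref = 1, exp = 0),
                                         kind = "categorical"), cur), 0)
  ## unnormalised curve is rejected
  expect_error(compute_paf(expo, rr_curve(c("ref", "exp"), c(1, 2),
                                          "categorical")),
               class = "dm_domain_error")
})

test_that("continuous PAFs agree with a Monte-Carlo counterfactual", {
  set.seed(88)
  for (k in 1:5) {
    grid <- seq(15, 45, 1)
    slope <- runif(1, 0.02, 0.12)
    tm <- runif(1, 18, 24)
    cur <- normalize_rr(rr_curve(grid, exp(slope * pmax(grid - tm, 0))), tm)
    mu <- runif(1, 22, 32)
    expo <- dmburden:::normal_exposure(grid, mu, runif(1, 2, 5))
    paf <- compute_paf(expo, cur)
    ## counterfactual simulation: incidence proportional to RR; moving all
    ## exposure to the TMREL removes the PAF share of cases
    n <- 2e5
    x <- sample(grid, n, replace = TRUE,
                prob = expo$x / sum(expo$x))
    rr_i <- approx(cur$grid, cur$rr, x, rule = 2)$y
    cases <- mean(rr_i)         # factual cases per unit baseline risk
    mc_paf <- (cases - 1) / cases
    mc_se <- sd(rr_i) / sqrt(n) / cases
    expect_lt(abs(paf - mc_paf), 3 * mc_se + 0.01)
  }
})

test_that("shifting exposure mass to higher RR never lowers the PAF", {
  grid <- seq(0, 10, 0.5)
  cur <- normalize_rr(rr_curve(grid, exp(0.2 * grid)), 0)
  p1 <- compute_paf(dmburden:::normal_exposure(grid, 3, 1.5), cur)
  p2 <- compute_paf(dmburden:::normal_exposure(grid, 5, 1.5), cur)
  expect_gt(p2, p1)
})

test_that("attributable burden is PAF times DALYs draw-wise", {
  keys <- tibble::tibble(location_id = 1:2)
  paf <- drawset(keys, matrix(c(0.5, 0.4, 0.5, 0.6), 2))
  daly <- drawset(keys, matrix(1000, 2, 2))
  ab <- attributable_burden(paf, daly)
  expect_equal(ab$draws, matrix(c(500, 400, 500, 600), 2))
  expect_equal(mean(ab$draws[2, ]), 500)
  zero <- drawset(keys, matrix(0, 2, 2))
  expect_true(all(attributable_burden(zero, daly)$draws == 0))
})

test_that("PAF aggregation uses the independence approximation", {
  keys <- tibble::tibble(location_id = 1L)
  p <- function(v) drawset(keys, matrix(v, 1, 2))
  expect_equal(aggregate_pafs(list(p(0.3)))$draws[1, ], c(0.3, 0.3))
  expect_equal(aggregate_pafs(list(p(0.5), p(0.5)))$draws[1, ],
               c(0.75, 0.75))
  ## zero PAF is the neutral element
  expect_equal(aggregate_pafs(list(p(0.3), p(0)))$draws,
               aggregate_pafs(list(p(0.3)))$draws)
  ## combined >= max individual when all non-negative
  set.seed(9)
  vals <- runif(5, 0, 0.4)
  comb <- aggregate_pafs(lapply(vals, p))$draws[1, 1]
  expect_gte(comb, max(vals))
  expect_lt(comb, 1)
  expect_error(aggregate_pafs(list(p(1.0))), class = "dm_domain_error")
})

test_that("PAF percentage change is computed draw-wise", {
  keys <- tibble::tibble(location_id = 1L)
  t0 <- drawset(keys, matrix(c(0.4, 0.5), 1))
  t1 <- drawset(keys, matrix(c(0.5, 0.55), 1))
  ch <- paf_percentage_change(t0, t1)
  expect_equal(ch$draws[1, ], c(25, 10))
  same <- paf_percentage_change(t0, t0)
  expect_equal(same$draws[1, ], c(0, 0))
  expect_error(paf_percentage_change(drawset(keys, matrix(c(0, 0.5), 1)),
                                     t1),
               class = "dm_config_error")
})

test_that("the registry exposes 16 risks with type attachments", {
  w <- tiny_world()
  expect_length(w$risks, 16)
  applies <- vapply(w$risks, `[[`, character(1), "applies")
  expect_equal(sum(applies == "both"), 2)  # the two temperature risks
  expect_true(all(grepl("temperature", names(which(applies == "both")))))
  ## every risk yields finite PAF draws strictly below 1
  for (rn in names(w$risks)) {
    d <- risk_paf_draws(w$risks, rn, 1, 2021, n = 10, seed = 3)
    expect_true(all(is.finite(d)))
    expect_true(all(d < 1))
    expect_true(all(d > -1))
  }
})
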