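## Illness-death (susceptible/case) compartmental model. Rates are
## piecewise-constant on the age grid, so within each age segment the system
##   dS/da = -(i + m) S + r C
##   dC/da =  i S - (r + m + f) C
## is linear with constant coefficients and is propagated exactly with the
## closed-form 2x2 matrix exponential. Off-diagonal entries (i, r) are
## non-negative, so the eigenvalues are always real.

## Vectorised exp([[a, b], [c, d]]) over segments, written via
## phi = expm1(2*disc)/(2*disc) so the equal-eigenvalue limit is smooth.
seg_expm <- function(a, b, c, d) {
  hd <- (a - d) / 2
  disc <- sqrt(pmax(hd^2 + b * c, 0))
  e2 <- exp((a + d) / 2 - disc)
  phi <- ifelse(disc > 0, expm1(2 * disc) / (2 * disc), 1)
  mid <- e2 * (1 + disc * phi)
  list(
    e11 = hd * e2 * phi + mid,
    e12 = b * e2 * phi,
    e21 = c * e2 * phi,
    e22 = -hd * e2 * phi + mid
  )
}

## Propagate (S, C) across segments with transition matrices `tm`.
propagate_sc <- function(tm, s0, c0) {
  n <- length(tm$e11)
  S <- C <- numeric(n + 1)
  S[1] <- s0
  C[1] <- c0
  for (k in seq_len(n)) {
    S[k + 1] <- tm$e11[k] * S[k] + tm$e12[k] * C[k]
    C[k + 1] <- tm$e21[k] * S[k] + tm$e22[k] * C[k]
  }
  list(S = S, C = C)
}

## Lean solver core used inside optimisation loops: no validation, no
## tibble construction. One closed-form expm per half segment (the full
## segment step is the half step applied twice). Returns prevalence at
## group midpoints and at edges.
illness_death_core <- function(i, r, f, m, widths) {
  hw <- widths / 2
  a <- -(i + m) * hw
  b <- r * hw
  cc <- i * hw
  d <- -(r + m + f) * hw
  hd <- (a - d) / 2
  disc <- sqrt(hd * hd + b * cc)
  e2 <- exp((a + d) / 2 - disc)
  pos <- disc > 0
  phi <- rep(1, length(disc))
  phi[pos] <- expm1(2 * disc[pos]) / (2 * disc[pos])
  ep <- e2 * phi
  mid <- e2 + disc * ep
  h11 <- hd * ep + mid
  h12 <- b * ep
  h21 <- cc * ep
  h22 <- mid - hd * ep
  G <- length(widths)
  p_mid <- numeric(G)
  p_edges <- numeric(G + 1)
  S <- 1; C <- 0
  for (k in seq_len(G)) {
    sm <- h11[k] * S + h12[k] * C
    cm <- h21[k] * S + h22[k] * C
    tm <- sm + cm
    p_mid[k] <- if (tm > 0) cm / tm else 0
    S <- h11[k] * sm + h12[k] * cm
    C <- h21[k] * sm + h22[k] * cm
    te <- S + C
    p_edges[k + 1] <- if (te > 0) C / te else 0
  }
  list(p_mid = p_mid, p_edges = p_edges)
}

#' Solve the illness-death model for prevalence and cause-specific mortality
#'
#' Integrates the two-compartment susceptible/case system along age for one
#' birth cohort (period approximation: rates fixed at one calendar year),
#' with rates constant within each age group. The solution is exact per
#' segment (closed-form matrix exponential). Prevalence is reported at the
#' midpoint of each age group; the open-ended top group uses a width of 5
#' years for integration and start + 2.5 years as its midpoint.
#'
#' @param incidence,remission,excess_mort,background_mort non-negative
#'   per-age-group rate vectors (events per person-year), one value per age
#'   group of `age_edges`.
#' @param age_edges strictly increasing lower edges of the age groups; the
#'   top group is open-ended.
#' @param p0 prevalence at age 0 (default 0).
#' @return A tibble (the rate bundle) with columns `age_start`, `age_end`,
#'   the four input rates, `prevalence` (proportion at group midpoint) and
#'   `csmr` (= prevalence x excess_mort, deaths per person-year). Attributes
#'   `age_edges` and `p_edges` carry the exact solution at the grid edges
#'   (including the top group's closing edge).
#' @export
solve_illness_death <- function(incidence, remission, excess_mort,
                                background_mort, age_edges, p0 = 0) {
  check_age_edges(age_edges)
  G <- length(age_edges)
  rates <- list(incidence = incidence, remission = remission,
                excess_mort = excess_mort, background_mort = background_mort)
  for (nm in names(rates)) {
    v <- rates[[nm]]
    if (length(v) != G) {
      dm_abort(sprintf("%s must have one value per age group (%d)", nm, G),
               "dm_config_error")
    }
    if (any(!is.finite(v)) || any(v < 0)) {
      dm_abort(sprintf("%s must be non-negative and finite", nm),
               "dm_domain_error")
    }
  }
  if (p0 < 0 || p0 > 1) dm_abort("p0 must be in [0, 1]", "dm_domain_error")

  widths <- c(diff(age_edges), 5)
  i <- incidence; r <- remission; f <- excess_mort; m <- background_mort
  A <- function(dt) seg_expm(-(i + m) * dt, r * dt, i * dt, -(r + m + f) * dt)
  full <- propagate_sc(A(widths), 1 - p0, p0)
  ## midpoint state: propagate the stored edge state half a segment forward
  half <- A(widths / 2)
  Smid <- half$e11 * full$S[-(G + 1)] + half$e12 * full$C[-(G + 1)]
  Cmid <- half$e21 * full$S[-(G + 1)] + half$e22 * full$C[-(G + 1)]

  p_mid <- safe_prevalence(Smid, Cmid)
  p_edges <- safe_prevalence(full$S, full$C)

  out <- tibble::tibble(
    age_start = age_edges,
    age_end = c(age_edges[-1], Inf),
    incidence = i, remission = r,
    excess_mort = f, background_mort = m,
    prevalence = p_mid,
    csmr = p_mid * f
  )
  attr(out, "age_edges") <- c(age_edges, age_edges[G] + 5)
  attr(out, "p_edges") <- p_edges
  out
}

safe_prevalence <- function(S, C) {
  tot <- S + C
  if (any(tot <= 0)) {
    warn("cohort mass underflowed to 0; prevalence set to 0 there",
         class = "dm_underflow_warning")
  }
  ifelse(tot > 0, C / tot, 0)
}

#' Draw-level subtraction of type 1 prevalence from total diabetes
#'
#' Type 2 is defined residually: total minus type 1, floored at zero per
#' draw per cell. Below age 15 all prevalence is assigned to type 1 before
#' subtraction, so type 2 is zero there.
#'
#' @param total,type1 aligned prevalence [drawset]s.
#' @return A [drawset] of type 2 prevalence with attribute `n_clamped`, the
#'   number of (cell, draw) entries floored at zero (diagnostic).
#' @export
subtract_type1 <- function(total, type1) {
  t1 <- align_drawsets(total, type1)
  d1 <- t1$draws
  if ("age_start" %in% names(total$keys)) {
    under15 <- total$keys$age_start < 15
    d1[under15, ] <- total$draws[under15, ]
  }
  diff <- total$draws - d1
  n_clamped <- sum(diff < 0)
  out <- drawset(total$keys, pmax(diff, 0))
  attr(out, "n_clamped") <- n_clamped
  out
}
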