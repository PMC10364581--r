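## Shared fixtures: tiny worlds and rate curves built in code.

tiny_config <- function(...) {
  world_config(n_locations = 2L, age_edges = seq(0, 90, 10),
               years = 2019:2021, n_draws = 20L, seed = 99L, ...)
}

tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_world(tiny_config())
    cache
  }
})

## smooth test rate curves on an age grid
test_rates <- function(edges) {
  mids <- (edges + c(edges[-1], edges[length(edges)] + 5)) / 2
  list(
    i = 0.012 * plogis((mids - 45) / 12),
    f = 0.01 + 3e-4 * mids,
    m = pmin(8e-4 * exp(0.073 * mids), 0.7)
  )
}

## Fine-grid forward-Euler oracle computed without looping: within each
## constant-rate segment the Euler iterate is (I + hA)^n, evaluated by
## repeated squaring. Bit-compatible with literal stepping up to roundoff,
## so very small h is affordable.
euler_power_oracle <- function(i, r, f, m, edges, h = 1e-6, p0 = 0) {
  widths <- c(diff(edges), 5)
  v <- c(1 - p0, p0)
  p_edges <- numeric(length(edges) + 1)
  p_edges[1] <- p0
  for (g in seq_along(widths)) {
    A <- matrix(c(-(i[g] + m[g]), i[g], r[g], -(r[g] + m[g] + f[g])), 2, 2)
    M <- diag(2) + h * A
    n <- round(widths[g] / h)
    P <- diag(2)
    while (n > 0) {
      if (n %% 2 == 1) P <- P %*% M
      M <- M %*% M
      n <- n %/% 2
    }
    v <- P %*% v
    p_edges[g + 1] <- if (sum(v) > 0) v[2] / sum(v) else 0
  }
  p_edges
}

## independent fine-grid forward-Euler oracle for the illness-death model;
## rates piecewise constant on age groups, step h years
euler_illness_death <- function(i, r, f, m, edges, h = 0.001, p0 = 0) {
  widths <- c(diff(edges), 5)
  bounds <- cumsum(c(0, widths))
  S <- 1 - p0; C <- p0
  p_edges <- numeric(length(edges) + 1)
  p_edges[1] <- p0
  for (g in seq_along(widths)) {
    n_step <- round(widths[g] / h)
    for (s in seq_len(n_step)) {
      dS <- -(i[g] + m[g]) * S + r[g] * C
      dC <- i[g] * S - (r[g] + m[g] + f[g]) * C
      S <- S + h * dS
      C <- C + h * dC
    }
    p_edges[g + 1] <- if (S + C > 0) C / (S + C) else 0
  }
  p_edges
}
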