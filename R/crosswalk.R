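## Case-definition crosswalks: robust (least-trimmed-squares) estimation of
## the log-ratio between each alternate diabetes definition and the FPG
## reference from matched pairs, adjustment of datapoints onto the
## reference scale, and conversion of mean-FPG-only reports to prevalence.

## Least-trimmed-squares location estimate of y: retain h = n - ceil(trim*n)
## points minimising the retained sum of squared residuals about their own
## mean. Exhaustive subset search for n <= 20; iterated concentration steps
## with random restarts above that (deterministic via a fixed local seed).
lts_location <- function(y, trim, n_restarts = 20L, seed = 7L) {
  n <- length(y)
  n_trim <- ceiling(trim * n)
  h <- n - n_trim
  if (h < 2) dm_abort("too few points retained after trimming",
                      "dm_config_error")
  if (n_trim == 0) {
    keep <- seq_len(n)
  } else if (n <= 20) {
    subsets <- combn(n, h)
    rss <- apply(subsets, 2, function(ix) sum((y[ix] - mean(y[ix]))^2))
    keep <- subsets[, which.min(rss)]
  } else {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
    best <- NULL
    best_rss <- Inf
    for (s in seq_len(n_restarts)) {
      keep_s <- sample.int(n, h)
      repeat {   # concentration: keep the h smallest residuals, iterate
        mu <- mean(y[keep_s])
        nxt <- order(abs(y - mu))[seq_len(h)]
        if (setequal(nxt, keep_s)) break
        keep_s <- nxt
      }
      rss <- sum((y[keep_s] - mean(y[keep_s]))^2)
      if (rss < best_rss) {
        best_rss <- rss
        best <- keep_s
      }
    }
    keep <- best
  }
  retained <- sort(keep)
  est <- mean(y[retained])
  se <- if (length(retained) > 1) sd(y[retained]) / sqrt(length(retained))
        else 0
  list(estimate = est, se = se, retained = retained,
       trimmed = setdiff(seq_len(n), retained))
}

#' Estimate definition log-ratios by trimmed meta-regression
#'
#' For each alternate case definition, the log-ratio to the reference is the
#' least-trimmed-squares location of log(alternate) - log(reference) over
#' matched pairs: exactly `ceiling(trim_fraction * n)` pairs are excluded,
#' chosen to minimise the trimmed sum of squared residuals (exhaustive
#' subset search for n <= 20, concentration steps otherwise). The standard
#' error comes from the retained pairs. The reference definition always has
#' log-ratio 0 with SE 0.
#'
#' @param pairs tibble of matched observations with columns `definition`,
#'   `ref_value`, `alt_value` (both positive prevalences).
#' @param trim_fraction proportion trimmed, in \[0, 0.5) (default 0.10).
#' @param reference label of the reference definition (default "fpg").
#' @return A tibble, one row per definition (reference first): `definition`,
#'   `log_ratio`, `se`, `n_pairs`, and a list-column `trimmed` of trimmed
#'   pair indices (within that definition's pairs) for audit.
#' @export
estimate_definition_ratios <- function(pairs, trim_fraction = 0.10,
                                       reference = "fpg") {
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    dm_abort("trim_fraction must be in [0, 0.5)", "dm_config_error")
  }
  defs <- unique(pairs$definition)
  rows <- lapply(defs, function(d) {
    sub <- pairs[pairs$definition == d, ]
    if (nrow(sub) < 5) {
      dm_abort(sprintf("need >= 5 pairs for definition '%s', got %d", d,
                       nrow(sub)), "dm_config_error")
    }
    y <- log(sub$alt_value) - log(sub$ref_value)
    res <- lts_location(y, trim_fraction)
    tibble::tibble(definition = d, log_ratio = res$estimate, se = res$se,
                   n_pairs = nrow(sub), trimmed = list(res$trimmed))
  })
  dplyr::bind_rows(
    tibble::tibble(definition = reference, log_ratio = 0, se = 0,
                   n_pairs = NA_integer_, trimmed = list(integer())),
    dplyr::bind_rows(rows)
  )
}

#' Adjust datapoints to the reference case definition
#'
#' Multiplies each observation by exp(-log_ratio) of its definition and
#' inflates its uncertainty by the ratio's standard error via the delta
#' method in log space, so the relative standard error never decreases.
#' Reference-definition datapoints pass through unchanged.
#'
#' @param datapoints tibble with `definition`, `value`, `se`.
#' @param ratios output of [estimate_definition_ratios].
#' @return The datapoints with adjusted `value` and `se`; original columns
#'   preserved as `value_orig`, `se_orig`.
#' @export
adjust_datapoints <- function(datapoints, ratios) {
  miss <- setdiff(unique(datapoints$definition), ratios$definition)
  if (length(miss) > 0) {
    dm_abort(sprintf("no crosswalk ratio for definition '%s'", miss[1]),
             "dm_config_error")
  }
  idx <- match(datapoints$definition, ratios$definition)
  lr <- ratios$log_ratio[idx]
  lr_se <- ratios$se[idx]
  out <- datapoints
  out$value_orig <- datapoints$value
  out$se_orig <- datapoints$se
  out$value <- datapoints$value * exp(-lr)
  rel_se2 <- ifelse(datapoints$value > 0,
                    (datapoints$se / datapoints$value)^2, 0)
  out$se <- ifelse(datapoints$value > 0,
                   out$value * sqrt(rel_se2 + lr_se^2),
                   datapoints$se * exp(-lr))
  out
}

#' Convert a mean-FPG report to a diabetes prevalence
#'
#' Prevalence is the upper-tail probability of the population FPG
#' distribution above the diagnostic threshold (7 mmol/L). The population
#' distribution family is lognormal by default (parameterised by the
#' reported mean and SD on the natural scale) with normal as an option.
#'
#' @param mean_fpg population mean FPG (mmol/L), positive.
#' @param spread population SD of FPG (mmol/L), positive.
#' @param threshold diagnostic threshold (default 7 mmol/L).
#' @param family "lognormal" (default) or "normal".
#' @return prevalence proportion in (0, 1).
#' @export
mean_fpg_to_prevalence <- function(mean_fpg, spread, threshold = 7,
                                   family = c("lognormal", "normal")) {
  family <- match.arg(family)
  if (any(mean_fpg <= 0) || any(spread <= 0)) {
    dm_abort("mean_fpg and spread must be positive", "dm_config_error")
  }
  if (family == "normal") {
    return(pnorm(threshold, mean_fpg, spread, lower.tail = FALSE))
  }
  sigma2 <- log(1 + (spread / mean_fpg)^2)
  mu <- log(mean_fpg) - sigma2 / 2
  plnorm(threshold, mu, sqrt(sigma2), lower.tail = FALSE)
}
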