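## Deaths coded to unspecified diabetes type are split into type 1 / type 2
## with a log-linear regression of the type-2 share among type-coded deaths
## on age, sex and obesity prevalence, trained only on country-years with
## believable type-specific coding, and with all deaths under age 15
## assigned to type 1.

#' Select country-years usable for training the type-split model
#'
#' Applies both inclusion filters to a cell-level death table: (1) more than
#' 50% of the country-year's diabetes deaths carry a specific type code;
#' (2) among type-specific deaths of people older than 25 years, at least
#' 70% are coded to type 2. Cells of country-years failing either filter are
#' dropped; one message per exclusion names the failing filter.
#'
#' @param deaths tibble with columns `location_id`, `year`, `age_start`,
#'   `deaths_type1`, `deaths_type2`, `deaths_unspecified`.
#' @param coded_min minimum coded fraction (default 0.5, strict >).
#' @param type2_min minimum type-2 share of coded deaths over age 25
#'   (default 0.7, >=).
#' @param quiet suppress the per-exclusion messages.
#' @return The filtered tibble (all cells of retained country-years), with
#'   attribute `excluded`: a tibble of excluded country-years and the filter
#'   that removed them.
#' @export
select_training_rows <- function(deaths, coded_min = 0.5, type2_min = 0.7,
                                 quiet = FALSE) {
  if (!"age_start" %in% names(deaths)) {
    dm_abort("death table lacks age information (age_start)",
             "dm_schema_error")
  }
  cy <- deaths |>
    dplyr::group_by(.data$location_id, .data$year) |>
    dplyr::summarise(
      coded = sum(.data$deaths_type1 + .data$deaths_type2),
      total = sum(.data$deaths_type1 + .data$deaths_type2 +
                    .data$deaths_unspecified),
      t2_o25 = sum(.data$deaths_type2[.data$age_start >= 25]),
      coded_o25 = sum((.data$deaths_type1 +
                         .data$deaths_type2)[.data$age_start >= 25]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      coded_frac = ifelse(.data$total > 0, .data$coded / .data$total, 0),
      t2_frac_o25 = ifelse(.data$coded_o25 > 0,
                           .data$t2_o25 / .data$coded_o25, 0),
      pass1 = .data$coded_frac > coded_min,
      pass2 = .data$t2_frac_o25 >= type2_min
    )
  excluded <- cy |>
    dplyr::filter(!.data$pass1 | !.data$pass2) |>
    dplyr::mutate(filter = ifelse(!.data$pass1,
                                  "coded fraction <= 50%",
                                  "type-2 share of coded deaths over 25 < 70%"))
  if (!quiet) {
    for (k in seq_len(nrow(excluded))) {
      message(sprintf("excluding location %d year %d: %s",
                      excluded$location_id[k], excluded$year[k],
                      excluded$filter[k]))
    }
  }
  keep <- cy |> dplyr::filter(.data$pass1 & .data$pass2)
  out <- dplyr::semi_join(deaths, keep, by = c("location_id", "year"))
  attr(out, "excluded") <-
    excluded[, c("location_id", "year", "filter")]
  out
}

#' Fit the unspecified-type split model
#'
#' Regresses the type-2 proportion among type-coded deaths on age (age-group
#' indicators, so the strongly saturating age pattern is not forced through
#' a linear term), sex and obesity prevalence. "Log-linear" is taken
#' literally: a linear model of log(proportion), with a Duan smearing
#' retransformation factor and predictions clamped to \[0, 1\]; a
#' logit-link variant is available. Cells under age 15 and cells without
#' coded deaths are excluded from training (the under-15 split is fixed,
#' not modelled).
#'
#' @param training cell-level death table (see [select_training_rows]) with
#'   an `obesity` column (join the covariate before calling) and a `sex`
#'   column.
#' @param link "log" (default) or "logit".
#' @param min_rows minimum training rows (default 10).
#' @return Object of class `type_split_model`: the fitted `lm`, the link,
#'   coefficient table, and counts of rows used.
#' @export
fit_type_split <- function(training, link = c("log", "logit"),
                           min_rows = 10L) {
  link <- match.arg(link)
  if (!"obesity" %in% names(training)) {
    dm_abort("training table needs an 'obesity' covariate column",
             "dm_schema_error")
  }
  dat <- training |>
    dplyr::filter(.data$age_start >= 15,
                  .data$deaths_type1 + .data$deaths_type2 > 0) |>
    dplyr::mutate(
      share = .data$deaths_type2 /
        (.data$deaths_type1 + .data$deaths_type2),
      age_grp = factor(.data$age_start),
      y = if (link == "log") log(pmax(.data$share, 1e-6)) else
        qlogis(pmin(pmax(.data$share, 1e-6), 1 - 1e-6))
    )
  if (nrow(dat) < min_rows) {
    dm_abort(sprintf("need at least %d training rows, got %d", min_rows,
                     nrow(dat)), "dm_config_error")
  }
  X <- stats::model.matrix(~ age_grp + sex + obesity, data = dat)
  cn <- kappa(X, exact = TRUE)
  if (cn > 1e10) {
    dm_abort(sprintf("collinear design (condition number %.3g)", cn),
             "dm_fit_error")
  }
  fit <- lm(y ~ age_grp + sex + obesity, data = dat)
  ci <- suppressWarnings(suppressMessages(confint(fit)))
  ## Duan smearing factor: corrects the retransformation bias of
  ## exp(E[log share]) under the log link (1 for logit)
  smear <- if (link == "log") mean(exp(stats::residuals(fit))) else 1
  structure(list(
    fit = fit, link = link, smear = smear,
    age_levels = as.numeric(levels(dat$age_grp)),
    n_rows = nrow(dat), condition_number = cn,
    coefficients = coef(fit),
    obesity_coef = coef(fit)[["obesity"]],
    obesity_ci = ci["obesity", ]
  ), class = "type_split_model")
}

#' @export
print.type_split_model <- function(x, ...) {
  cat(sprintf(
    "<type_split_model (%s link): %d rows, obesity coef %.4f [%.4f, %.4f]>\n",
    x$link, x$n_rows, x$obesity_coef, x$obesity_ci[1], x$obesity_ci[2]))
  invisible(x)
}

#' Predict the type-2 share for demographic cells
#'
#' @param model a `type_split_model`.
#' @param cells tibble with `age_start`, `age_end`, `sex`, `obesity`.
#' @return numeric vector in \[0, 1\]; exactly 0 under age 15.
#' @export
predict_type2_share <- function(model, cells) {
  ## snap to the nearest trained age group so prediction never fails on an
  ## age level unseen in training
  lv <- model$age_levels
  snap <- lv[pmax(findInterval(cells$age_start, lv), 1)]
  hi <- pmin(findInterval(cells$age_start, lv) + 1, length(lv))
  use_hi <- abs(lv[hi] - cells$age_start) < abs(cells$age_start - snap)
  snap[use_hi] <- lv[hi][use_hi]
  cells <- dplyr::mutate(cells,
                         age_grp = factor(snap, levels = lv))
  eta <- unname(predict(model$fit, newdata = cells))
  share <- if (model$link == "log") {
    pmin(pmax(exp(eta) * model$smear, 0), 1)
  } else plogis(eta)
  ifelse(cells$age_start < 15, 0, share)
}

#' Redistribute unspecified-type deaths
#'
#' Splits each cell's unspecified deaths by the model-predicted type-2
#' share, then forces all under-15 deaths (coded and unspecified) to type 1.
#' Fractional deaths are allowed; the per-cell total is conserved exactly.
#'
#' @param deaths cell-level death table with coded and unspecified counts.
#' @param model a `type_split_model`.
#' @param covariates tibble with `location_id`, `year`, `obesity` to supply
#'   the covariate at prediction time.
#' @return The table with final `deaths_type1`, `deaths_type2` (no
#'   unspecified column) and unchanged `deaths_total`.
#' @export
redistribute_unspecified <- function(deaths, model, covariates) {
  tab <- dplyr::left_join(deaths,
                          covariates[, c("location_id", "year", "obesity")],
                          by = c("location_id", "year"))
  if (anyNA(tab$obesity)) {
    dm_abort("obesity covariate missing for some country-years",
             "dm_alignment_error")
  }
  share <- predict_type2_share(model, tab)
  total <- tab$deaths_type1 + tab$deaths_type2 + tab$deaths_unspecified
  t2 <- tab$deaths_type2 + tab$deaths_unspecified * share
  t1 <- total - t2
  under15 <- tab$age_start < 15
  t1[under15] <- total[under15]
  t2[under15] <- 0
  out <- deaths
  out$deaths_type1 <- t1
  out$deaths_type2 <- t2
  out$deaths_unspecified <- NULL
  out$deaths_total <- total
  out
}
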