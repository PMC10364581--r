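## DALY accounting: YLLs from deaths and a standard life table, YLDs from
## sequela prevalence and disability weights with multiplicative comorbidity
## correction, DALYs as their sum, plus the standard population and
## age-standardised rates.

#' Years of life lost
#'
#' YLL = deaths x standard remaining life expectancy at the representative
#' age of death (age-group midpoint; the open-ended top group uses start +
#' 2.5 years), draw-wise.
#'
#' @param deaths a [drawset] of death counts keyed by demographic cell.
#' @param life_table tibble with `age_start`, `life_exp` covering every age
#'   group present in `deaths`.
#' @return A YLL [drawset] on the same grid.
#' @export
compute_yll <- function(deaths, life_table) {
  idx <- match(deaths$keys$age_start, life_table$age_start)
  if (anyNA(idx)) {
    dm_abort(sprintf("life table missing age group starting at %s",
                     deaths$keys$age_start[which(is.na(idx))[1]]),
             "dm_config_error")
  }
  drawset(deaths$keys, deaths$draws * life_table$life_exp[idx])
}

## Comorbidity-corrected per-case disability for one sequela against a
## background disability b: combined multiplicative disability of the pair,
## allocated to the sequela proportionally to its own DW.
##   combined = 1 - (1 - dw)(1 - b);  share = dw / (dw + b)
comorbidity_corrected_dw <- function(dw, b) {
  ifelse(dw + b > 0, (1 - (1 - dw) * (1 - b)) * dw / (dw + b), 0)
}

#' Years lived with disability
#'
#' Sequelae partition prevalent cases (split proportions summing to <= 1);
#' raw YLD per sequela is prevalence x split x DW x population. Comorbidity
#' with background disability is corrected by combining each sequela's DW
#' with the per-capita background disability multiplicatively (independence
#' assumption) and allocating the combined disability proportionally to the
#' component DWs, which never increases YLD.
#'
#' @param prevalence a [drawset] of case prevalence (proportion).
#' @param sequelae tibble with `sequela`, `dw` in (0,1), `split` in \[0,1\],
#'   splits summing to <= 1.
#' @param population tibble on the same demographic grid with `value` =
#'   persons.
#' @param background_yld_per_capita scalar or [drawset]: average background
#'   (non-diabetes) disability per person, used as the comorbid disability
#'   weight; 0 disables the correction.
#' @return A YLD [drawset].
#' @export
compute_yld <- function(prevalence, sequelae, population,
                        background_yld_per_capita = 0) {
  if (any(sequelae$dw <= 0 | sequelae$dw >= 1)) {
    dm_abort("disability weights must lie in (0, 1)", "dm_config_error")
  }
  if (any(sequelae$split < 0) || sum(sequelae$split) > 1 + 1e-12) {
    dm_abort("sequela splits must be proportions summing to <= 1",
             "dm_config_error")
  }
  pop <- align_table(prevalence$keys, population)
  b <- if (inherits(background_yld_per_capita, "drawset")) {
    align_drawsets(prevalence, background_yld_per_capita)$draws
  } else background_yld_per_capita
  per_case <- 0
  for (k in seq_len(nrow(sequelae))) {
    per_case <- per_case +
      sequelae$split[k] * comorbidity_corrected_dw(sequelae$dw[k], b)
  }
  drawset(prevalence$keys, prevalence$draws * per_case * pop)
}

## match a value table onto a key grid
align_table <- function(keys, tab) {
  idx <- match(key_string(keys), key_string(tab[names(keys)]))
  if (anyNA(idx)) {
    dm_abort("table does not cover all demographic cells",
             "dm_alignment_error")
  }
  tab$value[idx]
}

#' Disability-adjusted life-years
#'
#' DALY = YLL + YLD, draw-wise on aligned grids.
#'
#' @param yll,yld aligned [drawset]s.
#' @return A DALY [drawset].
#' @export
compute_daly <- function(yll, yld) ds_combine(yll, yld, `+`)

#' Build the standard population for age-standardisation
#'
#' The per-age weight is the unweighted mean of the age-proportional
#' population distributions of all locations whose total population at the
#' reference year strictly exceeds the threshold (5 million persons).
#'
#' @param population tibble with demographic keys and `value` (persons) at
#'   one reference year (sexes are summed).
#' @param threshold minimum total population (strict >, default 5e6).
#' @return tibble `age_start`, `weight`; weights sum to 1.
#' @export
build_standard_population <- function(population, threshold = 5e6) {
  by_loc <- population |>
    dplyr::group_by(.data$location_id, .data$age_start) |>
    dplyr::summarise(pop = sum(.data$value), .groups = "drop_last") |>
    dplyr::mutate(total = sum(.data$pop), share = .data$pop / .data$total) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$total > threshold)
  if (nrow(by_loc) == 0) {
    dm_abort(sprintf(
      "no location exceeds the %g-person threshold", threshold),
      "dm_config_error")
  }
  by_loc |>
    dplyr::group_by(.data$age_start) |>
    dplyr::summarise(weight = mean(.data$share), .groups = "drop")
}

#' Age-standardise age-specific rates
#'
#' AS rate = sum over age of weight x age-specific rate, draw-wise.
#'
#' @param rates a [drawset] whose keys include `age_start` (one row per age
#'   group within each stratum defined by the other key columns).
#' @param std standard population from [build_standard_population]; must
#'   cover every age group in `rates`.
#' @return A [drawset] keyed by the non-age key columns.
#' @export
age_standardise <- function(rates, std) {
  idx <- match(rates$keys$age_start, std$age_start)
  if (anyNA(idx)) {
    dm_abort("standard population does not cover all age groups",
             "dm_alignment_error")
  }
  w <- std$weight[idx]
  keep <- setdiff(names(rates$keys), c("age_start", "age_end"))
  weighted <- drawset(rates$keys[keep], rates$draws * w)
  if (length(keep) == 0) {
    return(drawset(tibble::tibble(location_id = 0L),
                   matrix(colSums(weighted$draws), nrow = 1)))
  }
  ds_aggregate(weighted, keep)
}

#' Convert counts to rates per 100 000
#'
#' @param count a [drawset] of event counts.
#' @param population tibble on the same grid with `value` = persons (> 0
#'   wherever counts are nonzero).
#' @return A [drawset] of rates per 100 000 person-years.
#' @export
rate_per_100k <- function(count, population) {
  pop <- align_table(count$keys, population)
  if (any(pop <= 0 & rowSums(abs(count$draws)) > 0)) {
    dm_abort("zero population with nonzero counts", "dm_domain_error")
  }
  drawset(count$keys, sweep(count$draws, 1, ifelse(pop > 0, pop, 1), "/") *
            1e5)
}
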