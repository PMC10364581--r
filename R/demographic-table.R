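## The universal exchange object: one value of one measure per
## location x age-group x sex x year cell, as a tidy tibble.

DEMO_KEYS <- c("location_id", "age_start", "age_end", "sex", "year")

#' Build a demographic grid
#'
#' Expands locations, age groups, sexes and years into the tidy key grid used
#' by every table in the package. Age groups are taken from consecutive edges;
#' the top group is open-ended (`age_end = Inf`).
#'
#' @param location_ids integer vector of location identifiers.
#' @param age_edges strictly increasing numeric vector of age-group lower
#'   edges in years (e.g. `seq(0, 95, 5)`); the last group is open-ended.
#' @param sexes character vector, subset of `c("male", "female")`.
#' @param years integer vector of calendar years.
#' @return A tibble with columns `location_id`, `age_start`, `age_end`,
#'   `sex`, `year`, one row per cell.
#' @export
demographic_grid <- function(location_ids, age_edges,
                             sexes = c("male", "female"), years) {
  check_age_edges(age_edges)
  groups <- age_groups_from_edges(age_edges)
  tidyr::expand_grid(
    location_id = as.integer(location_ids),
    groups,
    sex = sexes,
    year = as.integer(years)
  )
}

age_groups_from_edges <- function(age_edges) {
  tibble::tibble(
    age_start = age_edges,
    age_end = c(age_edges[-1], Inf)
  )
}

check_age_edges <- function(age_edges) {
  if (length(age_edges) < 1 || any(diff(age_edges) <= 0)) {
    dm_abort("age_group_edges must be strictly increasing", "dm_config_error")
  }
  invisible(age_edges)
}

## Midpoint convention: representative age of a group; the open-ended top
## group uses start + 2.5 years.
age_midpoint <- function(age_start, age_end) {
  ifelse(is.finite(age_end), (age_start + age_end) / 2, age_start + 2.5)
}

#' Write / read a demographic table as tidy CSV
#'
#' The on-disk schema is one row per
#' (location_id, age_start, age_end, sex, year, measure, value\[, se\]).
#' Missing values are forbidden.
#'
#' @param tab tibble with the demographic key columns, a `measure` column and
#'   a `value` column (optionally `se`).
#' @param path file path.
#' @return `write_demo_csv` returns `path` invisibly; `read_demo_csv`
#'   returns the tibble.
#' @export
write_demo_csv <- function(tab, path) {
  stopifnot(all(c(DEMO_KEYS, "measure", "value") %in% names(tab)))
  if (anyNA(tab)) dm_abort("missing values are forbidden in the CSV schema",
                           "dm_schema_error")
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_demo_csv
#' @export
read_demo_csv <- function(path) {
  tab <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (anyNA(tab)) dm_abort("missing values are forbidden in the CSV schema",
                           "dm_schema_error")
  tab
}
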