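## DrawSet: a demographic table whose cells hold N-draw vectors.
## Internally a tibble of keys plus an (n_cells x n_draws) matrix, so
## draw-wise arithmetic is a single vectorised operation.

#' Construct a DrawSet
#'
#' A DrawSet pairs a tibble of demographic keys with a matrix of Monte-Carlo
#' draws (one row per cell, one column per draw). All pipeline uncertainty is
#' carried this way; every operation is draw-wise and any operation that
#' would change the number of draws fails loudly.
#'
#' @param keys tibble of key columns (any subset of
#'   location_id/age_start/age_end/sex/year, possibly with extra id columns).
#' @param draws numeric matrix with `nrow(keys)` rows.
#' @return An object of class `drawset`.
#' @export
drawset <- function(keys, draws) {
  keys <- tibble::as_tibble(keys)
  draws <- as.matrix(draws)
  if (nrow(keys) != nrow(draws)) {
    dm_abort("keys and draws must have the same number of rows",
             "dm_alignment_error")
  }
  structure(list(keys = keys, draws = unname(draws)), class = "drawset")
}

#' @export
print.drawset <- function(x, ...) {
  cat(sprintf("<drawset: %d cells x %d draws>\n", nrow(x$keys), n_draws(x)))
  print(utils::head(x$keys, 4))
  invisible(x)
}

#' Number of draws in a DrawSet
#' @param ds a `drawset`.
#' @return integer draw count.
#' @export
n_draws <- function(ds) ncol(ds$draws)

key_string <- function(keys) {
  do.call(paste, c(as.list(keys), sep = "|"))
}

## Reorder b's rows to match a's keys; error naming offending cells.
align_drawsets <- function(a, b) {
  if (!identical(sort(names(a$keys)), sort(names(b$keys)))) {
    dm_abort("drawsets have different key columns", "dm_alignment_error")
  }
  if (n_draws(a) != n_draws(b)) {
    dm_abort(sprintf("draw counts differ (%d vs %d)", n_draws(a), n_draws(b)),
             "dm_alignment_error")
  }
  idx <- match(key_string(a$keys), key_string(b$keys[names(a$keys)]))
  if (anyNA(idx) || nrow(a$keys) != nrow(b$keys)) {
    bad <- key_string(a$keys)[is.na(idx)]
    dm_abort(paste0("demographic grids are misaligned; cells missing from ",
                    "second argument: ",
                    paste(utils::head(bad, 5), collapse = ", ")),
             "dm_alignment_error")
    }
  drawset(b$keys[idx, , drop = FALSE], b$draws[idx, , drop = FALSE])
}

#' Combine two aligned DrawSets draw-wise
#'
#' @param a,b `drawset` objects on the same demographic grid with the same
#'   draw count.
#' @param f vectorised binary function applied element-wise.
#' @return A `drawset` on `a`'s grid.
#' @export
ds_combine <- function(a, b, f) {
  b <- align_drawsets(a, b)
  drawset(a$keys, f(a$draws, b$draws))
}

#' Apply a vectorised function to every draw
#' @param ds a `drawset`.
#' @param f vectorised function.
#' @return A `drawset`.
#' @export
ds_map <- function(ds, f) drawset(ds$keys, f(ds$draws))

#' @export
`+.drawset` <- function(e1, e2) ds_combine(e1, e2, `+`)

#' @export
`-.drawset` <- function(e1, e2) ds_combine(e1, e2, `-`)

#' @export
`*.drawset` <- function(e1, e2) {
  if (is.numeric(e2)) return(ds_map(e1, function(d) d * e2))
  if (is.numeric(e1)) return(ds_map(e2, function(d) d * e1))
  ds_combine(e1, e2, `*`)
}

#' Turn a demographic table of point values into a degenerate DrawSet
#'
#' Replicates a `value` column across `n` identical draws; used where a
#' quantity enters the pipeline without sampling uncertainty.
#'
#' @param tab tibble with key columns and a `value` column.
#' @param n draw count.
#' @return A `drawset`.
#' @export
as_drawset <- function(tab, n = 100L) {
  keys <- tab[setdiff(names(tab), "value")]
  drawset(keys, matrix(tab$value, nrow = nrow(tab), ncol = n))
}

#' Aggregate a DrawSet over key columns (draw-wise sums)
#'
#' @param ds a `drawset`.
#' @param by character vector of key columns to keep; all others are summed
#'   out draw-wise. Empty `by` collapses to a single global cell.
#' @return A `drawset` keyed by `by` (plus a `location_id = 0L` global row
#'   when `by` is empty).
#' @export
ds_aggregate <- function(ds, by = character()) {
  if (length(by) == 0) {
    keys <- tibble::tibble(location_id = 0L)
    return(drawset(keys, matrix(colSums(ds$draws), nrow = 1)))
  }
  ks <- key_string(ds$keys[by])
  agg <- rowsum(ds$draws, ks)   # rows ordered by sort(unique(ks))
  keys <- ds$keys[by][!duplicated(ks), , drop = FALSE]
  ord <- order(key_string(keys))
  drawset(keys[ord, , drop = FALSE], agg)
}
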