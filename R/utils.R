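#' Integer percentage, rounding half away from zero
#'
#' Converts a count pair into the integer percentage convention used throughout
#' the census tables: `round(100 * n / d)` with ties at .5 rounded away from
#' zero. R's `round()` rounds half to even, which would print 0.5% as 0%;
#' prevalence tables in this field report 21%, 43%, 14% etc. from their count
#' pairs, and half-away-from-zero reproduces every such printed value
#' deterministically.
#'
#' @param n Numerator count (detected, occurrences, ...).
#' @param d Denominator count; must be positive.
#' @return Integer percentage(s).
#' @examples
#' pct_round(59, 278) # 21
#' pct_round(10, 23)  # 43
#' @export
pct_round <- function(n, d) {
  if (any(d <= 0)) abort("pct_round(): denominator must be positive")
  x <- 100 * n / d
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# stop with a cell-addressed message during table validation
validation_error <- function(path, row, col, msg) {
  abort(sprintf("%s: row %d, column '%s': %s", path, row, col, msg))
}

# ids must be character, unique, non-missing
check_ids <- function(x, what) {
  if (anyNA(x) || any(!nzchar(x))) {
    abort(sprintf("%s ids must be non-missing, non-empty strings", what))
  }
  invisible(x)
}

taxonomic_ranks <- c("domain", "phylum", "class", "order", "family",
                     "genus", "species")

#' Split GTDB-style lineage strings into rank columns
#'
#' Lineages are 7-rank, semicolon-separated strings in GTDB order
#' (`d__...;p__...;c__...;o__...;f__...;g__...;s__...`). Rank prefixes
#' (`d__` etc.) are stripped if present. Missing trailing ranks become `""`,
#' matching GTDB's convention for, e.g., MAG-only genera without a genus name.
#'
#' @param mag_id Character vector of genome ids.
#' @param lineage Character vector of lineage strings, same length.
#' @return A tibble with columns `mag_id` and the 7 ranks.
#' @export
parse_lineage <- function(mag_id, lineage) {
  check_ids(mag_id, "mag")
  parts <- stringr::str_split(lineage, ";")
  rows <- purrr::map(parts, function(p) {
    p <- stringr::str_trim(p)
    p <- stringr::str_remove(p, "^[dpcofgs]__")
    length(p) <- 7L
    p[is.na(p)] <- ""
    setNames(as.list(p), taxonomic_ranks)
  })
  dplyr::bind_cols(tibble(mag_id = mag_id), dplyr::bind_rows(rows))
}
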