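#' Genome quality score
#'
#' The standard single-number genome quality score,
#' `completeness - 5 * contamination`, with both inputs in percent. A score of
#' at least 50 ("QS50") is the inclusion threshold for the MAG catalogue.
#'
#' @param completeness Completeness percentage(s) in \[0, 100\].
#' @param contamination Contamination percentage(s), >= 0.
#' @return Numeric quality score(s).
#' @examples
#' quality_score(95, 10) # 45: near-complete yet below QS50
#' @export
quality_score <- function(completeness, contamination) {
  if (any(completeness < 0 | completeness > 100, na.rm = TRUE)) {
    abort("quality_score(): completeness must lie in [0, 100]")
  }
  if (any(contamination < 0, na.rm = TRUE)) {
    abort("quality_score(): contamination must be >= 0")
  }
  completeness - 5 * contamination
}

#' @rdname quality_score
#' @details `passes_qs50()` is inclusive at the boundary: a score of exactly
#'   50 passes. `is_near_complete()` implements the stricter selection used
#'   for functional annotation: completeness >= 95 and contamination <= 10,
#'   both inclusive and configurable.
#' @param min_completeness,max_contamination Near-complete bounds (percent).
#' @export
passes_qs50 <- function(completeness, contamination) {
  quality_score(completeness, contamination) >= 50
}

#' @rdname quality_score
#' @export
is_near_complete <- function(completeness, contamination,
                             min_completeness = 95, max_contamination = 10) {
  if (any(completeness < 0 | completeness > 100, na.rm = TRUE)) {
    abort("is_near_complete(): completeness must lie in [0, 100]")
  }
  completeness >= min_completeness & contamination <= max_contamination
}

#' Remove duplicated samples from a manifest
#'
#' Sequence archives occasionally hold the same metagenome under two
#' accessions. Given the manifest and a table of identified duplicate pairs,
#' exactly one member of each connected group of duplicates is retained.
#' The member named in an optional `keep` column is retained when given;
#' otherwise the lexicographically smallest id in the group is kept, which
#' makes the reduction deterministic. Chains (A = B, B = C) are resolved
#' transitively: one sample survives per connected component.
#'
#' @param manifest A tibble with a `sample_id` column.
#' @param duplicate_pairs A tibble with columns `sample_a`, `sample_b` and
#'   optionally `keep` (one of the two ids). May have zero rows.
#' @return A list with `manifest` (retained rows, original order) and
#'   `removals` (tibble of `kept`, `removed`).
#' @export
deduplicate_samples <- function(manifest, duplicate_pairs) {
  stopifnot(is.data.frame(manifest), "sample_id" %in% names(manifest))
  check_ids(manifest$sample_id, "sample")
  if (anyDuplicated(manifest$sample_id)) {
    abort("deduplicate_samples(): manifest sample_id values must be unique")
  }
  if (is.null(duplicate_pairs) || nrow(duplicate_pairs) == 0L) {
    return(list(manifest = manifest,
                removals = tibble(kept = character(), removed = character())))
  }
  stopifnot(all(c("sample_a", "sample_b") %in% names(duplicate_pairs)))
  pair_ids <- c(duplicate_pairs$sample_a, duplicate_pairs$sample_b)
  unknown <- setdiff(pair_ids, manifest$sample_id)
  if (length(unknown) > 0L) {
    abort(sprintf("deduplicate_samples(): duplicate pair references unknown sample id(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  g <- igraph::graph_from_data_frame(
    duplicate_pairs[, c("sample_a", "sample_b")], directed = FALSE)
  comp <- igraph::components(g)
  membership <- comp$membership
  keep_flag <- if ("keep" %in% names(duplicate_pairs)) {
    stats::na.omit(unique(duplicate_pairs$keep))
  } else {
    character()
  }
  removals <- purrr::map(seq_len(comp$no), function(k) {
    ids <- sort(names(membership)[membership == k])
    flagged <- intersect(keep_flag, ids)
    kept <- if (length(flagged) >= 1L) sort(flagged)[1L] else ids[1L]
    tibble(kept = kept, removed = setdiff(ids, kept))
  })
  removals <- dplyr::bind_rows(removals)
  list(
    manifest = manifest[!(manifest$sample_id %in% removals$removed), , drop = FALSE],
    removals = removals
  )
}

# symmetric pair key
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Greedy dereplication of MAGs into species-level clusters
#'
#' Mirrors score-ranked, centroid-style dereplication: MAGs are sorted by
#' descending quality score (ties broken by ascending id) and each MAG joins
#' the first already-founded representative to which it has ANI >= `ani_min`
#' and alignment fraction >= `af_min`; otherwise it founds its own cluster.
#' ANI records are symmetrized, taking the maximum AF of the two directions;
#' a pair absent from the table is treated as below threshold. The defaults
#' are the species thresholds used for prokaryotes (95% ANI, 30% AF);
#' eukaryote catalogues use `af_min = 40`.
#'
#' @param mags A tibble with columns `mag_id`, `completeness`,
#'   `contamination`, and optionally `domain`.
#' @param ani A tibble with columns `mag_a`, `mag_b`, `ani`, `af`
#'   (all percentages).
#' @param ani_min,af_min Clustering thresholds in percent.
#' @return An object of class `derep_result`: list with `clusters` (tibble of
#'   `representative`, `member`, `ani`, `af`), `representatives` (character),
#'   and `species_table` (per-domain representative counts when `domain` is
#'   available).
#' @export
dereplicate <- function(mags, ani, ani_min = 95, af_min = 30) {
  stopifnot(is.data.frame(mags),
            all(c("mag_id", "completeness", "contamination") %in% names(mags)))
  check_ids(mags$mag_id, "mag")
  if (anyDuplicated(mags$mag_id)) abort("dereplicate(): duplicate mag_id in input")
  if (is.null(ani) || nrow(ani) == 0L) {
    ani <- tibble(mag_a = character(), mag_b = character(),
                  ani = numeric(), af = numeric())
  }
  stopifnot(all(c("mag_a", "mag_b", "ani", "af") %in% names(ani)))
  if (any(ani$ani > 100 | ani$ani < 0)) abort("dereplicate(): ANI must lie in [0, 100]")
  if (any(ani$af > 100 | ani$af < 0)) abort("dereplicate(): AF must lie in [0, 100]")

  sym <- ani |>
    mutate(key = pair_key(.data$mag_a, .data$mag_b)) |>
    group_by(.data$key) |>
    summarise(ani = max(.data$ani), af = max(.data$af), .groups = "drop")
  ani_lookup <- setNames(sym$ani, sym$key)
  af_lookup <- setNames(sym$af, sym$key)

  ord <- mags |>
    mutate(score = quality_score(.data$completeness, .data$contamination)) |>
    arrange(desc(.data$score), .data$mag_id)

  reps <- character()
  assign_rep <- character(nrow(ord))
  assign_ani <- rep(NA_real_, nrow(ord))
  assign_af <- rep(NA_real_, nrow(ord))
  for (i in seq_len(nrow(ord))) {
    id <- ord$mag_id[i]
    joined <- FALSE
    for (r in reps) {
      key <- pair_key(id, r)
      a <- ani_lookup[key]
      f <- af_lookup[key]
      if (!is.na(a) && !is.na(f) && a >= ani_min && f >= af_min) {
        assign_rep[i] <- r
        assign_ani[i] <- unname(a)
        assign_af[i] <- unname(f)
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, id)
      assign_rep[i] <- id
      assign_ani[i] <- 100
      assign_af[i] <- 100
    }
  }
  clusters <- tibble(representative = assign_rep, member = ord$mag_id,
                     ani = assign_ani, af = assign_af) |>
    arrange(.data$representative, .data$member)
  species_table <- if ("domain" %in% names(mags)) {
    mags |>
      filter(.data$mag_id %in% reps) |>
      count(.data$domain, name = "n_species") |>
      arrange(.data$domain)
  } else {
    tibble(domain = NA_character_, n_species = length(reps))
  }
  structure(
    list(clusters = clusters, representatives = reps,
         species_table = species_table,
         ani_min = ani_min, af_min = af_min),
    class = "derep_result"
  )
}

#' @export
print.derep_result <- function(x, ...) {
  cat(sprintf("<derep_result: %d MAGs in %d species clusters (ANI >= %g%%, AF >= %g%%)>\n",
              nrow(x$clusters), length(x$representatives), x$ani_min, x$af_min))
  invisible(x)
}

#' @describeIn dereplicate One row per member MAG with its representative.
#' @param x A `derep_result`.
#' @param ... Unused.
#' @method tidy derep_result
#' @export
tidy.derep_result <- function(x, ...) {
  x$clusters
}

#' @describeIn dereplicate One-row summary: input MAGs, clusters, thresholds.
#' @method glance derep_result
#' @export
glance.derep_result <- function(x, ...) {
  tibble(n_mags = nrow(x$clusters),
         n_clusters = length(x$representatives),
         ani_min = x$ani_min, af_min = x$af_min)
}
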