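census_levels <- c("species", "genus", "family", "order", "class", "phylum")

# taxon label of each MAG at a rank, with the genus fallback
# "<Family> gen. sp." for MAGs lacking a genus-level assignment
taxon_label_at <- function(taxonomy, level) {
  if (!level %in% census_levels) {
    abort(sprintf("unknown taxonomic level '%s' (use one of %s)",
                  level, paste(census_levels, collapse = ", ")))
  }
  if (level == "species") {
    return(setNames(taxonomy$mag_id, taxonomy$mag_id))
  }
  lab <- taxonomy[[level]]
  if (level == "genus") {
    blank <- is.na(lab) | !nzchar(lab)
    lab[blank] <- paste(taxonomy$family[blank], "gen. sp.")
  }
  setNames(lab, taxonomy$mag_id)
}

#' Tabulate occurrence frequency at a taxonomic level
#'
#' Frequency is the total number of occurrences (present sample x species
#' pairs) across the data set. For levels above species, occurrences of all
#' member species-level lineages are summed; the number of distinct member
#' lineages with at least one occurrence is reported alongside. MAGs without
#' a genus assignment are tabulated at genus level under
#' `"<Family> gen. sp."`. Prevalence is the integer percentage of samples in
#' the denominator in which at least one member lineage is present.
#'
#' @param occ A `lichen_occurrence` (see [call_occurrence()]).
#' @param taxonomy A tibble with `mag_id` and the 7 rank columns; every
#'   species in the occurrence universe must be present.
#' @param level One of `"species"`, `"genus"`, `"family"`, `"order"`,
#'   `"class"`, `"phylum"`.
#' @param sample_subset Optional sample ids forming the prevalence
#'   denominator (e.g. Dataset 1); defaults to the full sample universe.
#' @return A tibble with `taxon`, `level`, `n_occurrences`, `n_lineages`,
#'   `n_samples`, `prevalence_pct`, `denominator`, sorted by descending
#'   `n_occurrences` (ties alphabetical).
#' @export
tabulate_frequency <- function(occ, taxonomy, level = "genus",
                               sample_subset = NULL) {
  stopifnot(inherits(occ, "lichen_occurrence"), is.data.frame(taxonomy))
  missing <- setdiff(occurrence_species(occ), taxonomy$mag_id)
  if (length(missing) > 0L) {
    abort(sprintf("tabulate_frequency(): %d species missing from taxonomy (e.g. %s)",
                  length(missing), missing[1L]))
  }
  samples <- occurrence_samples(occ)
  if (is.null(sample_subset)) sample_subset <- samples
  if (length(sample_subset) == 0L) abort("tabulate_frequency(): empty sample subset")
  labels <- taxon_label_at(taxonomy, level)
  pres <- present_calls(occ) |>
    filter(.data$sample_id %in% sample_subset) |>
    mutate(taxon = unname(labels[.data$mag_id]))
  denom <- length(unique(sample_subset))
  pres |>
    group_by(.data$taxon) |>
    summarise(
      n_occurrences = n(),
      n_lineages = n_distinct(.data$mag_id),
      n_samples = n_distinct(.data$sample_id),
      .groups = "drop"
    ) |>
    mutate(
      level = level,
      prevalence_pct = pct_round(.data$n_samples, denom),
      denominator = denom
    ) |>
    select("taxon", "level", "n_occurrences", "n_lineages", "n_samples",
           "prevalence_pct", "denominator") |>
    arrange(desc(.data$n_occurrences), .data$taxon)
}

#' Select the most frequent taxa and report their share
#'
#' Ranks a frequency table by descending occurrence count (alphabetical
#' tie-break) and reports, for the top `k` taxa, the integer-percent share of
#' species-level lineages and of occurrences they account for.
#'
#' @param freq Output of [tabulate_frequency()].
#' @param k Number of taxa to select; if larger than the table, all rows are
#'   returned with a warning.
#' @return A list with `top` (the selected rows, rank order),
#'   `lineage_share_pct`, and `occurrence_share_pct`.
#' @export
rank_and_select_top <- function(freq, k) {
  stopifnot(is.data.frame(freq),
            all(c("taxon", "n_occurrences", "n_lineages") %in% names(freq)))
  if (k < 1) abort("rank_and_select_top(): k must be >= 1")
  ranked <- freq |> arrange(desc(.data$n_occurrences), .data$taxon)
  if (k > nrow(ranked)) {
    warn(sprintf("rank_and_select_top(): k = %d exceeds the %d available taxa; returning all",
                 k, nrow(ranked)))
    k <- nrow(ranked)
  }
  top <- ranked |> slice_head(n = k)
  list(
    top = top,
    lineage_share_pct = pct_round(sum(top$n_lineages), sum(ranked$n_lineages)),
    occurrence_share_pct = pct_round(sum(top$n_occurrences), sum(ranked$n_occurrences))
  )
}

#' Merge MAG occurrence with rRNA screening into a three-tier detection table
#'
#' Detection of a taxon in a sample is recorded on three tiers: recovery as a
#' MAG (any member species present), detection of its SSU rRNA in the
#' assembly, and detection of its SSU rRNA in the raw reads. No inference is
#' made across tiers; each is reported as observed.
#'
#' @param occ A `lichen_occurrence`.
#' @param rrna A long tibble of rRNA screening results: `sample_id`,
#'   `mag_id` (the organism screened), `tier` (`"assembly"` or `"read"`),
#'   `detected` (logical). May have zero rows.
#' @param taxonomy Taxonomy covering every organism in `occ` and `rrna`.
#' @param level Rank at which organisms are rolled up into taxa.
#' @param taxa Optional focal taxa; defaults to all taxa observed.
#' @return A tibble `sample_id`, `taxon`, `mag`, `assembly_rrna`,
#'   `read_rrna`, complete over samples x taxa.
#' @export
merge_detection_tiers <- function(occ, rrna, taxonomy, level = "family",
                                  taxa = NULL) {
  stopifnot(inherits(occ, "lichen_occurrence"))
  if (is.null(rrna)) {
    rrna <- tibble(sample_id = character(), mag_id = character(),
                   tier = character(), detected = logical())
  }
  stopifnot(all(c("sample_id", "mag_id", "tier", "detected") %in% names(rrna)))
  ids <- union(occurrence_species(occ), unique(rrna$mag_id))
  missing <- setdiff(ids, taxonomy$mag_id)
  if (length(missing) > 0L) {
    abort(sprintf("merge_detection_tiers(): organism(s) absent from taxonomy: %s",
                  paste(head(missing, 3), collapse = ", ")))
  }
  labels <- taxon_label_at(taxonomy, level)
  samples <- occurrence_samples(occ)
  if (is.null(taxa)) taxa <- sort(unique(unname(labels[ids])))

  mag_hits <- present_calls(occ) |>
    mutate(taxon = unname(labels[.data$mag_id])) |>
    filter(.data$taxon %in% taxa) |>
    distinct(.data$sample_id, .data$taxon) |>
    mutate(mag = TRUE)
  rrna_hits <- rrna |>
    filter(.data$detected) |>
    mutate(taxon = unname(labels[.data$mag_id])) |>
    filter(.data$taxon %in% taxa, .data$sample_id %in% samples) |>
    distinct(.data$sample_id, .data$taxon, .data$tier) |>
    mutate(hit = TRUE) |>
    tidyr::pivot_wider(names_from = "tier", values_from = "hit",
                       values_fill = FALSE)
  for (col in c("assembly", "read")) {
    if (!col %in% names(rrna_hits)) rrna_hits[[col]] <- logical(nrow(rrna_hits))
  }
  tidyr::expand_grid(sample_id = samples, taxon = taxa) |>
    left_join(mag_hits, by = c("sample_id", "taxon")) |>
    left_join(rrna_hits, by = c("sample_id", "taxon")) |>
    mutate(
      mag = dplyr::coalesce(.data$mag, FALSE),
      assembly_rrna = dplyr::coalesce(.data$assembly, FALSE),
      read_rrna = dplyr::coalesce(.data$read, FALSE)
    ) |>
    select("sample_id", "taxon", "mag", "assembly_rrna", "read_rrna")
}

#' Prevalence of a taxon on one detection tier
#'
#' Integer-percent prevalence (rounding half away from zero, the convention
#' that reproduces all printed percentages from their count pairs) of a taxon
#' across a sample subset on a given detection tier.
#'
#' @param detection Output of [merge_detection_tiers()].
#' @param taxon The taxon to assess.
#' @param tier One of `"mag"`, `"assembly_rrna"`, `"read_rrna"`.
#' @param subset Optional sample ids forming the denominator (e.g. Dataset 1);
#'   defaults to all samples in the table. Must be non-empty.
#' @return A one-row tibble: `taxon`, `tier`, `n_detected`, `denominator`,
#'   `prevalence_pct`.
#' @export
prevalence <- function(detection, taxon,
                       tier = c("mag", "assembly_rrna", "read_rrna"),
                       subset = NULL) {
  tier <- match.arg(tier)
  stopifnot(is.data.frame(detection),
            all(c("sample_id", "taxon", tier) %in% names(detection)))
  rows <- detection |> filter(.data$taxon == .env$taxon)
  if (!is.null(subset)) rows <- rows |> filter(.data$sample_id %in% subset)
  denom <- n_distinct(rows$sample_id)
  if (denom == 0L) abort("prevalence(): empty sample subset for this taxon")
  detected <- rows |> filter(.data[[tier]]) |> pull("sample_id") |> n_distinct()
  tibble(taxon = taxon, tier = tier, n_detected = detected,
         denominator = denom, prevalence_pct = pct_round(detected, denom))
}

detection_outcomes <- c("mag_and_rrna", "mag_only", "rrna_only", "not_detected")

#' Classify the joint MAG/rRNA screening outcome
#'
#' Each sample x taxon record is classified from its MAG tier and read-tier
#' rRNA flags into one of `mag_and_rrna`, `mag_only`, `rrna_only`,
#' `not_detected`. With sequencing depths supplied, rows are ordered by
#' (taxon, outcome, depth descending), the layout used to display detection
#' against depth.
#'
#' @param detection Output of [merge_detection_tiers()].
#' @param depths Optional tibble `sample_id`, `total_depth_bp`.
#' @return The detection tibble with an ordered `outcome` factor (and
#'   `total_depth_bp` when depths are given).
#' @export
classify_detection_outcome <- function(detection, depths = NULL) {
  stopifnot(all(c("mag", "read_rrna") %in% names(detection)))
  out <- detection |>
    mutate(outcome = factor(
      dplyr::case_when(
        .data$mag & .data$read_rrna ~ "mag_and_rrna",
        .data$mag ~ "mag_only",
        .data$read_rrna ~ "rrna_only",
        TRUE ~ "not_detected"
      ),
      levels = detection_outcomes
    ))
  if (!is.null(depths)) {
    stopifnot(all(c("sample_id", "total_depth_bp") %in% names(depths)))
    out <- out |>
      left_join(depths[, c("sample_id", "total_depth_bp")], by = "sample_id") |>
      arrange(.data$taxon, .data$outcome, desc(.data$total_depth_bp))
  }
  out
}

#' Build a co-occurrence network from presence records
#'
#' Co-occurrence is an instance of two lineages occurring together in one
#' metagenome; edge weight counts the samples shared by a pair. Zero-weight
#' pairs are omitted, as are lineages present in no sample. Node classes
#' (e.g. symbiont roles, with the LFS as anchor) annotate the vertices.
#'
#' @param x Presence records: either a `lichen_occurrence` (present species
#'   are the lineages) or a tibble with columns `sample_id` and `lineage`,
#'   one row per presence instance.
#' @param focal Optional lineages to restrict the network to.
#' @param node_classes Optional tibble `lineage`, `class` for vertex
#'   annotation.
#' @param sample_subset Optional sample ids (e.g. Dataset 2) to restrict the
#'   co-occurrence counting to.
#' @return An object of class `cooccurrence_network`: list with `nodes`
#'   (`lineage`, `class`, `n_samples`) and `edges` (`lineage_a`, `lineage_b`,
#'   `weight`), both alphabetically ordered, `lineage_a < lineage_b`.
#' @export
build_cooccurrence <- function(x, focal = NULL, node_classes = NULL,
                               sample_subset = NULL) {
  pres <- if (inherits(x, "lichen_occurrence")) {
    present_calls(x) |>
      select("sample_id", lineage = "mag_id")
  } else {
    stopifnot(is.data.frame(x), all(c("sample_id", "lineage") %in% names(x)))
    as_tibble(x[, c("sample_id", "lineage")])
  }
  if (!is.null(sample_subset)) pres <- pres |> filter(.data$sample_id %in% sample_subset)
  if (!is.null(focal)) {
    if (length(focal) == 0L) abort("build_cooccurrence(): focal set must be non-empty")
    pres <- pres |> filter(.data$lineage %in% focal)
  }
  pres <- distinct(pres)
  lineages <- sort(unique(pres$lineage))
  inc <- matrix(0L, nrow = n_distinct(pres$sample_id), ncol = length(lineages),
                dimnames = list(sort(unique(pres$sample_id)), lineages))
  inc[cbind(match(pres$sample_id, rownames(inc)),
            match(pres$lineage, colnames(inc)))] <- 1L
  shared <- crossprod(inc)
  idx <- which(upper.tri(shared) & shared >= 1, arr.ind = TRUE)
  edges <- tibble(
    lineage_a = lineages[idx[, 1L]],
    lineage_b = lineages[idx[, 2L]],
    weight = as.integer(shared[idx])
  ) |>
    arrange(.data$lineage_a, .data$lineage_b)
  nodes <- tibble(lineage = lineages,
                  n_samples = as.integer(diag(shared)))
  nodes$class <- if (!is.null(node_classes)) {
    stopifnot(all(c("lineage", "class") %in% names(node_classes)))
    node_classes$class[match(nodes$lineage, node_classes$lineage)]
  } else {
    NA_character_
  }
  structure(list(nodes = nodes[, c("lineage", "class", "n_samples")],
                 edges = edges),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("<cooccurrence_network: %d lineages, %d edges>\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @describeIn build_cooccurrence Weighted edge list.
#' @param ... Unused.
#' @method tidy cooccurrence_network
#' @export
tidy.cooccurrence_network <- function(x, ...) x$edges

#' @describeIn build_cooccurrence Convert to an igraph graph (weighted,
#'   undirected; isolated lineages kept as vertices).
#' @param net A `cooccurrence_network`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  igraph::graph_from_data_frame(
    net$edges |> rename(from = "lineage_a", to = "lineage_b"),
    directed = FALSE,
    vertices = net$nodes |> rename(name = "lineage")
  )
}

#' @describeIn build_cooccurrence Write the network as GraphML.
#' @param path Output file path.
#' @export
write_cooccurrence_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
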