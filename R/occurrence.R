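#' Depth of coverage of a genome
#'
#' Mean per-base coverage estimated from read counts: the number of aligned
#' reads multiplied by the read length and divided by the total length of the
#' genome (the contigs assigned to the MAG).
#'
#' @param n_reads Number of reads aligned to the MAG.
#' @param read_length Read length in bp.
#' @param mag_length Total MAG length in bp; must be positive.
#' @return Numeric depth(s) of coverage.
#' @examples
#' depth_of_coverage(1000, 150, 1.5e6) # 0.1
#' @export
depth_of_coverage <- function(n_reads, read_length, mag_length) {
  if (any(mag_length <= 0)) abort("depth_of_coverage(): mag_length must be positive")
  n_reads * read_length / mag_length
}

#' Relative abundance of a symbiont against the fungal host
#'
#' The ratio of a symbiont MAG's depth of coverage to the depth of the lichen
#' fungal symbiont (LFS) MAG in the same metagenome. A ratio of 1 means
#' coverage parity with the LFS; basidiomycete yeasts typically sit around
#' 0.01 (a 1:100 regime). Undefined (missing) when the LFS depth is zero.
#'
#' @param depth_symbiont,depth_lfs Depths of coverage.
#' @return Numeric ratio(s); `NA` where `depth_lfs` is 0.
#' @export
relative_abundance <- function(depth_symbiont, depth_lfs) {
  if (any(depth_symbiont < 0 | depth_lfs < 0, na.rm = TRUE)) {
    abort("relative_abundance(): depths must be >= 0")
  }
  ifelse(depth_lfs > 0, depth_symbiont / depth_lfs, NA_real_)
}

#' Call genome presence from breadth of coverage
#'
#' A species-representative MAG is counted as present in a metagenome when at
#' least `breadth_min` of its positions are covered by mapped reads
#' (inclusive at the boundary, default 50%). Sample/MAG pairs absent from the
#' coverage table are absent. The result is a long-form incidence table that
#' carries the full sample and species universes as attributes, so that
#' samples in which nothing was recovered keep contributing to denominators.
#'
#' @param coverage A tibble with columns `sample_id`, `mag_id`, `breadth`
#'   (fraction in \[0, 1\]); extra columns (e.g. `depth`) are carried along.
#' @param breadth_min Presence threshold in (0, 1\].
#' @param samples,species Optional full id universes (e.g. the manifest's
#'   sample list, including zero-MAG samples). Defaults to the ids observed
#'   in `coverage`.
#' @return A tibble of class `lichen_occurrence` with a logical `present`
#'   column; attributes `samples` and `species` hold the ordered universes.
#' @export
call_occurrence <- function(coverage, breadth_min = 0.5,
                            samples = NULL, species = NULL) {
  stopifnot(is.data.frame(coverage),
            all(c("sample_id", "mag_id", "breadth") %in% names(coverage)))
  if (!(breadth_min > 0 && breadth_min <= 1)) {
    abort("call_occurrence(): breadth_min must lie in (0, 1]")
  }
  bad <- which(coverage$breadth < 0 | coverage$breadth > 1 | is.na(coverage$breadth))
  if (length(bad) > 0L) {
    abort(sprintf("call_occurrence(): breadth outside [0, 1] at row %d", bad[1L]))
  }
  samples <- if (is.null(samples)) sort(unique(coverage$sample_id)) else unique(samples)
  species <- if (is.null(species)) sort(unique(coverage$mag_id)) else unique(species)
  extra <- setdiff(unique(coverage$sample_id), samples)
  if (length(extra) > 0L) {
    abort(sprintf("call_occurrence(): coverage has sample ids outside the sample universe: %s",
                  paste(head(extra, 3), collapse = ", ")))
  }
  occ <- coverage |>
    as_tibble() |>
    mutate(present = .data$breadth >= breadth_min) |>
    arrange(.data$sample_id, .data$mag_id)
  structure(occ,
            class = c("lichen_occurrence", class(tibble())),
            samples = samples, species = species,
            breadth_min = breadth_min)
}

#' @rdname call_occurrence
#' @param occ A `lichen_occurrence`.
#' @export
occurrence_samples <- function(occ) attr(occ, "samples")

#' @rdname call_occurrence
#' @export
occurrence_species <- function(occ) attr(occ, "species")

#' @rdname call_occurrence
#' @details `occurrence_matrix()` widens the call table into the strict
#'   binary sample x species incidence matrix.
#' @export
occurrence_matrix <- function(occ) {
  stopifnot(inherits(occ, "lichen_occurrence"))
  samples <- occurrence_samples(occ)
  species <- occurrence_species(occ)
  m <- matrix(0L, nrow = length(samples), ncol = length(species),
              dimnames = list(samples, species))
  pres <- occ[occ$present, c("sample_id", "mag_id")]
  m[cbind(match(pres$sample_id, samples), match(pres$mag_id, species))] <- 1L
  m
}

# present rows only, as a plain tibble
present_calls <- function(occ) {
  as_tibble(occ[occ$present, , drop = FALSE])
}

#' Assign the putative lichen fungal symbiont MAG per sample
#'
#' Among the fungal MAGs called present in a sample, the LFS candidate is the
#' one with the highest depth of coverage (the dominant fungus is expected to
#' have the deepest coverage); ties are broken by lexicographically smallest
#' `mag_id` for determinism. Samples without a present fungal MAG get status
#' `none_found`.
#'
#' @param occ A `lichen_occurrence` (see [call_occurrence()]).
#' @param depths A tibble `sample_id`, `mag_id`, `depth`. Missing pairs count
#'   as depth 0.
#' @param taxonomy A tibble with `mag_id` and `domain` (plus other ranks);
#'   fungal MAGs are rows with `domain == "Fungi"` (case-insensitive).
#' @return A tibble `sample_id`, `lfs_mag_id`, `depth`, `status`
#'   (`candidate` or `none_found`), one row per sample in the universe.
#' @export
assign_lfs <- function(occ, depths, taxonomy) {
  stopifnot(inherits(occ, "lichen_occurrence"),
            all(c("mag_id", "domain") %in% names(taxonomy)))
  fungal_ids <- taxonomy$mag_id[tolower(taxonomy$domain) == "fungi"]
  pres <- present_calls(occ) |>
    filter(.data$mag_id %in% fungal_ids) |>
    select("sample_id", "mag_id")
  if (!is.null(depths)) {
    stopifnot(all(c("sample_id", "mag_id", "depth") %in% names(depths)))
    pres <- pres |>
      left_join(depths[, c("sample_id", "mag_id", "depth")],
                by = c("sample_id", "mag_id")) |>
      mutate(depth = dplyr::coalesce(.data$depth, 0))
  } else {
    pres$depth <- 0
  }
  chosen <- pres |>
    arrange(.data$sample_id, desc(.data$depth), .data$mag_id) |>
    group_by(.data$sample_id) |>
    slice_head(n = 1L) |>
    ungroup() |>
    rename(lfs_mag_id = "mag_id") |>
    mutate(status = "candidate")
  tibble(sample_id = occurrence_samples(occ)) |>
    left_join(chosen, by = "sample_id") |>
    mutate(status = dplyr::coalesce(.data$status, "none_found"))
}

# lineage-consistency helper: expected genus for a declared lichen name
lookup_genus <- function(name, name_map) {
  i <- match(name, name_map$name)
  if (is.na(i)) NA_character_ else name_map$genus[i]
}

#' Verify LFS assignments against declared sample names
#'
#' The declared lichen name of each sample is resolved to an expected fungal
#' genus and compared with the lineage of the assigned LFS MAG
#' (lineage-consistency standing in for manual tree inspection). Outcomes:
#'
#' * `verified` — declared genus matches the candidate MAG's genus;
#' * `reassigned` — mismatch, but another present fungal MAG matches; the
#'   call moves to that MAG (deepest first, then smallest id);
#' * `name_corrected` — mismatch, but an alternate declared name
#'   (`library_name` in the manifest) resolves and matches the candidate;
#'   the sample is retained under the corrected name;
#' * `misassigned` — unresolved mismatch (or unresolvable declared name);
#'   the sample is flagged as potentially misidentified and later excluded
#'   from Dataset 2;
#' * `none_found` — carried through from [assign_lfs()].
#'
#' @param calls Output of [assign_lfs()].
#' @param manifest A tibble with `sample_id`, `declared_lfs_name`, and
#'   optionally `library_name`.
#' @param name_map A tibble mapping declared names to expected fungal genera:
#'   columns `name`, `genus`.
#' @param taxonomy MAG taxonomy with `mag_id`, `domain`, `genus`.
#' @param occ,depths Passed to consider alternative fungal MAGs for
#'   reassignment; may be `NULL` to skip the reassignment route.
#' @return The calls tibble with final `status`, possibly updated
#'   `lfs_mag_id`, plus `corrected_name` and `reason` columns.
#' @export
verify_lfs <- function(calls, manifest, name_map, taxonomy,
                       occ = NULL, depths = NULL) {
  stopifnot(all(c("sample_id", "lfs_mag_id", "status") %in% names(calls)),
            all(c("sample_id", "declared_lfs_name") %in% names(manifest)),
            all(c("name", "genus") %in% names(name_map)),
            all(c("mag_id", "genus") %in% names(taxonomy)))
  mag_genus <- setNames(taxonomy$genus, taxonomy$mag_id)
  has_library_name <- "library_name" %in% names(manifest)
  fungal_ids <- taxonomy$mag_id[tolower(taxonomy$domain) == "fungi"]

  pres_fungal <- if (!is.null(occ)) {
    pf <- present_calls(occ) |>
      filter(.data$mag_id %in% fungal_ids) |>
      select("sample_id", "mag_id")
    if (!is.null(depths)) {
      pf <- pf |>
        left_join(depths[, c("sample_id", "mag_id", "depth")],
                  by = c("sample_id", "mag_id")) |>
        mutate(depth = dplyr::coalesce(.data$depth, 0))
    } else {
      pf$depth <- 0
    }
    pf
  } else {
    NULL
  }

  out <- calls |>
    left_join(manifest[, intersect(names(manifest),
                                   c("sample_id", "declared_lfs_name", "library_name"))],
              by = "sample_id") |>
    mutate(corrected_name = NA_character_, reason = NA_character_)

  for (i in seq_len(nrow(out))) {
    if (out$status[i] != "candidate") next
    declared <- out$declared_lfs_name[i]
    expected <- lookup_genus(declared, name_map)
    if (is.na(expected)) {
      out$status[i] <- "misassigned"
      out$reason[i] <- sprintf("declared name '%s' could not be resolved to a lineage", declared)
      next
    }
    observed <- unname(mag_genus[out$lfs_mag_id[i]])
    if (!is.na(observed) && observed == expected) {
      out$status[i] <- "verified"
      next
    }
    # route 1: another present fungal MAG matches the declared name
    if (!is.null(pres_fungal)) {
      alts <- pres_fungal |>
        filter(.data$sample_id == out$sample_id[i],
               .data$mag_id != out$lfs_mag_id[i]) |>
        mutate(genus = unname(mag_genus[.data$mag_id])) |>
        filter(!is.na(.data$genus), .data$genus == expected) |>
        arrange(desc(.data$depth), .data$mag_id)
      if (nrow(alts) > 0L) {
        out$status[i] <- "reassigned"
        out$reason[i] <- sprintf("LFS call moved from %s to %s to match declared name '%s'",
                                 out$lfs_mag_id[i], alts$mag_id[1L], declared)
        out$lfs_mag_id[i] <- alts$mag_id[1L]
        out$depth[i] <- alts$depth[1L]
        next
      }
    }
    # route 2: alternate declared name from the library metadata
    if (has_library_name && !is.na(out$library_name[i]) &&
        nzchar(out$library_name[i])) {
      alt_expected <- lookup_genus(out$library_name[i], name_map)
      if (!is.na(alt_expected) && !is.na(observed) && observed == alt_expected) {
        out$status[i] <- "name_corrected"
        out$corrected_name[i] <- out$library_name[i]
        out$reason[i] <- sprintf("declared name '%s' corrected to library name '%s'",
                                 declared, out$library_name[i])
        next
      }
    }
    out$status[i] <- "misassigned"
    out$reason[i] <- sprintf("MAG lineage (genus %s) inconsistent with declared name '%s' (expected genus %s)",
                             ifelse(is.na(observed), "unknown", observed),
                             declared, expected)
  }
  out |>
    select("sample_id", "lfs_mag_id", "depth", "status", "corrected_name", "reason")
}

lfs_ok_statuses <- c("verified", "reassigned", "name_corrected")

#' Build the Dataset 1 / Dataset 2 filtering cascade
#'
#' Dataset 1 comprises the samples with at least one present MAG; Dataset 2
#' is the subset of Dataset 1 whose LFS call survived verification
#' (`verified`, `reassigned`, or `name_corrected`). The summary records the
#' progressive reduction of the sample set.
#'
#' @param manifest Deduplicated manifest with `sample_id`.
#' @param occ A `lichen_occurrence` whose sample universe covers the manifest.
#' @param lfs_calls Output of [verify_lfs()].
#' @return An object of class `dataset_cascade`: list with `labels` (tibble
#'   `sample_id`, `in_dataset1`, `in_dataset2`) and `summary` (one-row tibble
#'   with `n_total`, `n_no_mag`, `n_dataset1`, `n_with_fungal_mag`,
#'   `n_misassigned`, `n_dataset2`).
#' @export
build_dataset_cascade <- function(manifest, occ, lfs_calls) {
  stopifnot("sample_id" %in% names(manifest),
            inherits(occ, "lichen_occurrence"),
            all(c("sample_id", "status") %in% names(lfs_calls)))
  samples <- manifest$sample_id
  missing <- setdiff(samples, occurrence_samples(occ))
  if (length(missing) > 0L) {
    abort(sprintf("build_dataset_cascade(): %d manifest sample(s) missing from the occurrence universe (e.g. %s)",
                  length(missing), missing[1L]))
  }
  with_mag <- unique(present_calls(occ)$sample_id)
  status <- setNames(lfs_calls$status, lfs_calls$sample_id)
  labels <- tibble(sample_id = samples) |>
    mutate(
      in_dataset1 = .data$sample_id %in% with_mag,
      lfs_status = unname(status[.data$sample_id]),
      in_dataset2 = .data$in_dataset1 &
        !is.na(.data$lfs_status) & .data$lfs_status %in% lfs_ok_statuses
    )
  d1 <- labels$in_dataset1
  summary <- tibble(
    n_total = nrow(labels),
    n_no_mag = sum(!d1),
    n_dataset1 = sum(d1),
    n_with_fungal_mag = sum(d1 & !is.na(labels$lfs_status) &
                              labels$lfs_status != "none_found"),
    n_misassigned = sum(d1 & !is.na(labels$lfs_status) &
                          labels$lfs_status == "misassigned"),
    n_dataset2 = sum(labels$in_dataset2)
  )
  structure(list(labels = labels, summary = summary), class = "dataset_cascade")
}

#' @export
print.dataset_cascade <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<dataset_cascade: %d samples -> %d with a MAG (Dataset 1) -> %d with a verified LFS (Dataset 2)>\n",
              s$n_total, s$n_dataset1, s$n_dataset2))
  invisible(x)
}

#' @describeIn build_dataset_cascade Per-sample dataset labels.
#' @param x A `dataset_cascade`.
#' @param ... Unused.
#' @method tidy dataset_cascade
#' @export
tidy.dataset_cascade <- function(x, ...) x$labels

#' @describeIn build_dataset_cascade One-row cascade counts.
#' @method glance dataset_cascade
#' @export
glance.dataset_cascade <- function(x, ...) x$summary
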