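#' @title Table IO and the pipeline orchestrator
#'
#' @description
#' All tables move as UTF-8, tab-separated files with a header row and `.`
#' decimals. Readers validate against a named schema and report the first
#' offending row and column. The orchestrator chains the census stages in
#' order (deduplicate, call occurrence, assign/verify the LFS, build the
#' dataset cascade, tabulate the census, evaluate module completeness,
#' classify trophy status, assess complementarity) and records the cascade
#' counts in a run manifest.
#'
#' @name pipeline
NULL

# column types: c = character, d = double, i = integer, l = logical
census_schemas <- list(
  coverage = list(cols = c(sample_id = "c", mag_id = "c", breadth = "d",
                           depth = "d", n_reads = "d", read_length = "d",
                           mag_length = "d"),
                  required = c("sample_id", "mag_id", "breadth"),
                  range = list(breadth = c(0, 1)),
                  key = c("sample_id", "mag_id")),
  quality = list(cols = c(mag_id = "c", completeness = "d",
                          contamination = "d", domain = "c"),
                 required = c("mag_id", "completeness", "contamination"),
                 range = list(completeness = c(0, 100),
                              contamination = c(0, Inf)),
                 key = "mag_id"),
  taxonomy = list(cols = c(mag_id = "c", domain = "c", phylum = "c",
                           class = "c", order = "c", family = "c",
                           genus = "c", species = "c"),
                  required = c("mag_id", "domain"),
                  range = list(), key = "mag_id"),
  ko = list(cols = c(genome_id = "c", ko = "c"),
            required = c("genome_id", "ko"), range = list(),
            key = c("genome_id", "ko")),
  rrna = list(cols = c(sample_id = "c", mag_id = "c", tier = "c",
                       detected = "l"),
              required = c("sample_id", "mag_id", "tier", "detected"),
              range = list(), key = c("sample_id", "mag_id", "tier")),
  manifest = list(cols = c(sample_id = "c", declared_lfs_name = "c",
                           library_name = "c", total_depth_bp = "d",
                           read_length = "d", duplicate_of = "c",
                           misidentified = "l"),
                  required = "sample_id",
                  range = list(total_depth_bp = c(1e-9, Inf)),
                  key = "sample_id"),
  ani = list(cols = c(mag_a = "c", mag_b = "c", ani = "d", af = "d"),
             required = c("mag_a", "mag_b", "ani", "af"),
             range = list(ani = c(0, 100), af = c(0, 100)),
             key = c("mag_a", "mag_b")),
  truth = list(cols = c(sample_id = "c", organism_id = "c",
                        mass_fraction = "d", depth = "d", breadth = "d",
                        present = "l", read_rrna = "l", assembly_rrna = "l"),
               required = c("sample_id", "organism_id", "present"),
               range = list(breadth = c(0, 1), mass_fraction = c(0, 1)),
               key = c("sample_id", "organism_id"))
)

#' Read and validate a census table
#'
#' @param path Path to a TSV file.
#' @param schema One of `"coverage"`, `"quality"`, `"taxonomy"`, `"ko"`,
#'   `"rrna"`, `"manifest"`, `"ani"`, `"truth"`.
#' @return A typed tibble in file row order. Missing required columns,
#'   out-of-range values (e.g. a breadth of 1.2) and duplicated primary keys
#'   raise errors naming the offending cell.
#' @export
read_census_table <- function(path, schema) {
  if (!schema %in% names(census_schemas)) {
    abort(sprintf("unknown schema '%s' (use one of %s)", schema,
                  paste(names(census_schemas), collapse = ", ")))
  }
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  sc <- census_schemas[[schema]]
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(sc$required, names(tbl))
  if (length(missing) > 0L) {
    abort(sprintf("%s: missing required column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  for (col in intersect(names(tbl), names(sc$cols))) {
    type <- sc$cols[[col]]
    raw <- tbl[[col]]
    if (type == "d") {
      val <- suppressWarnings(as.numeric(raw))
      bad <- which(!is.na(raw) & nzchar(raw) & is.na(val))
      if (length(bad) > 0L) {
        validation_error(path, bad[1L], col,
                         sprintf("'%s' is not a number", raw[bad[1L]]))
      }
      tbl[[col]] <- val
    } else if (type == "l") {
      val <- toupper(raw) %in% c("TRUE", "T", "1")
      bad <- which(!is.na(raw) & !toupper(raw) %in%
                     c("TRUE", "FALSE", "T", "F", "1", "0"))
      if (length(bad) > 0L) {
        validation_error(path, bad[1L], col,
                         sprintf("'%s' is not a logical", raw[bad[1L]]))
      }
      val[is.na(raw)] <- NA
      tbl[[col]] <- val
    }
  }
  for (col in names(sc$range)) {
    if (!col %in% names(tbl)) next
    rng <- sc$range[[col]]
    bad <- which(!is.na(tbl[[col]]) & (tbl[[col]] < rng[1] | tbl[[col]] > rng[2]))
    if (length(bad) > 0L) {
      validation_error(path, bad[1L], col,
                       sprintf("value %s outside [%s, %s]",
                               format(tbl[[col]][bad[1L]]), rng[1], rng[2]))
    }
  }
  if (!is.null(sc$key) && all(sc$key %in% names(tbl))) {
    keys <- do.call(paste, c(tbl[sc$key], sep = "\r"))
    dup <- which(duplicated(keys))
    if (length(dup) > 0L) {
      validation_error(path, dup[1L], sc$key[1L], "duplicate primary key")
    }
  }
  tbl
}

#' Write / read a simulated bundle as a directory of TSV files
#'
#' @param bundle A `simulated_bundle` (see [generate_bundle()]).
#' @param dir Output directory (created if needed). Files written:
#'   `coverage.tsv`, `quality.tsv`, `taxonomy.tsv`, `ko.tsv`, `rrna.tsv`,
#'   `manifest.tsv`, `ani.tsv`, `truth.tsv`.
#' @return `write_bundle()`: the directory, invisibly. `read_bundle()`: a
#'   named list of validated tibbles.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "simulated_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(census_schemas)) {
    readr::write_tsv(bundle[[nm]], file.path(dir, paste0(nm, ".tsv")),
                     progress = FALSE)
  }
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  out <- purrr::map(names(census_schemas), function(nm) {
    read_census_table(file.path(dir, paste0(nm, ".tsv")), nm)
  })
  setNames(out, names(census_schemas))
}

#' Run the full census pipeline on a bundle
#'
#' Stages, in order: sample deduplication; presence calling at
#' `breadth_min`; LFS assignment and verification; the Dataset 1 / Dataset 2
#' cascade; frequency tabulation (genus level, Dataset 1 denominator);
#' detection-tier merging and outcome classification; a co-occurrence
#' network over Dataset 2; module completeness; trophy classification;
#' selection of highly complete metagenomes and complementarity assessment.
#' All outputs are deterministic functions of the bundle (sorted rows, fixed
#' rounding), so reruns are byte-identical.
#'
#' @param bundle A `simulated_bundle`, or an equivalent named list of tables
#'   (as from [read_bundle()]) plus `modules`, `rules`, `name_map`,
#'   `duplicate_pairs`, and an `organisms` roster with roles.
#' @param breadth_min Presence threshold; defaults to the bundle's
#'   configured threshold (0.5).
#' @param detection_level Rank for the detection-tier table.
#' @return A `census_run`: list with every stage output plus `run_manifest`
#'   (stage row counts and the cascade).
#' @export
run_census_pipeline <- function(bundle, breadth_min = NULL,
                                detection_level = "family") {
  breadth_min <- breadth_min %||% bundle$config$breadth_threshold %||% 0.5
  roles <- bundle$organisms |> select("organism_id", "role")

  dedup <- deduplicate_samples(bundle$manifest, bundle$duplicate_pairs)
  retained <- dedup$manifest$sample_id

  coverage <- bundle$coverage |> filter(.data$sample_id %in% retained)
  occ <- call_occurrence(coverage, breadth_min = breadth_min,
                         samples = retained,
                         species = bundle$organisms$organism_id)
  depths <- coverage |> select("sample_id", "mag_id", "depth")

  taxonomy <- bundle$taxonomy
  calls <- assign_lfs(occ, depths, taxonomy)
  calls <- verify_lfs(calls, dedup$manifest, bundle$name_map, taxonomy,
                      occ = occ, depths = depths)
  cascade <- build_dataset_cascade(dedup$manifest, occ, calls)
  dataset1 <- cascade$labels$sample_id[cascade$labels$in_dataset1]
  dataset2 <- cascade$labels$sample_id[cascade$labels$in_dataset2]

  frequency <- tabulate_frequency(occ, taxonomy, level = "genus",
                                  sample_subset = dataset1)
  rrna <- bundle$rrna |> filter(.data$sample_id %in% retained)
  detection <- merge_detection_tiers(occ, rrna, taxonomy,
                                     level = detection_level)
  outcomes <- classify_detection_outcome(
    detection, dedup$manifest[, c("sample_id", "total_depth_bp")])
  network <- build_cooccurrence(
    occ, sample_subset = dataset2,
    node_classes = roles |> rename(lineage = "organism_id", class = "role"))

  completeness <- completeness_table(bundle$modules, bundle$ko)
  trophy <- trophy_profiles(bundle$ko, bundle$rules, bundle$modules,
                            genome_ids = bundle$organisms$organism_id)

  qualifying <- select_highly_complete_metagenomes(
    occ, bundle$quality, roles |> rename(mag_id = "organism_id"))
  qualified_ids <- qualifying$sample_id[qualifying$qualifies]
  role_of <- setNames(roles$role, roles$organism_id)
  complementarity <- purrr::map(qualified_ids, function(s) {
    mags <- qualifying$mag_ids[[match(s, qualifying$sample_id)]]
    members <- trophy |>
      filter(.data$genome_id %in% mags) |>
      mutate(role = unname(role_of[.data$genome_id]))
    # one LFS profile per qualifying sample by construction
    assess_complementarity(members, sample_id = s)
  })
  complementarity <- dplyr::bind_rows(complementarity)

  run_manifest <- dplyr::bind_cols(
    tibble(n_input_samples = nrow(bundle$manifest),
           n_duplicates_removed = nrow(dedup$removals)),
    cascade$summary,
    tibble(n_species = length(occurrence_species(occ)),
           n_qualifying = length(qualified_ids))
  )

  structure(
    list(dedup = dedup, occurrence = occ, lfs_calls = calls,
         cascade = cascade, frequency = frequency, detection = detection,
         outcomes = outcomes, network = network,
         completeness = completeness, trophy = trophy,
         qualifying = qualifying, complementarity = complementarity,
         run_manifest = run_manifest),
    class = "census_run"
  )
}

#' @export
print.census_run <- function(x, ...) {
  m <- x$run_manifest
  cat(sprintf("<census_run: %d samples -> Dataset 1 = %d, Dataset 2 = %d, %d species, %d highly complete metagenomes>\n",
              m$n_input_samples, m$n_dataset1, m$n_dataset2, m$n_species,
              m$n_qualifying))
  invisible(x)
}

#' @describeIn run_census_pipeline One-row run manifest (stage counts).
#' @param x A `census_run`.
#' @param ... Unused.
#' @method glance census_run
#' @export
glance.census_run <- function(x, ...) x$run_manifest

# list columns collapsed for serialization
flatten_list_cols <- function(tbl) {
  for (col in names(tbl)) {
    if (is.list(tbl[[col]])) {
      tbl[[col]] <- purrr::map_chr(tbl[[col]], paste, collapse = ";")
    }
  }
  tbl
}

#' Write every stage output of a run as sorted TSV files
#'
#' Outputs are written with sorted primary keys and fixed formatting, so a
#' rerun of the same bundle produces byte-identical files.
#'
#' @param run A `census_run`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_census_outputs <- function(run, dir) {
  stopifnot(inherits(run, "census_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(tbl, name) {
    readr::write_tsv(flatten_list_cols(tbl), file.path(dir, name),
                     progress = FALSE)
  }
  w(as_tibble(run$occurrence) |> arrange(.data$sample_id, .data$mag_id),
    "occurrence.tsv")
  w(run$lfs_calls |> arrange(.data$sample_id), "lfs_calls.tsv")
  w(run$cascade$labels |> arrange(.data$sample_id), "datasets.tsv")
  w(run$frequency, "frequency.tsv")
  w(run$detection |> arrange(.data$sample_id, .data$taxon), "detection.tsv")
  w(run$outcomes, "outcomes.tsv")
  w(run$network$edges, "network_edges.tsv")
  w(run$completeness |> arrange(.data$genome_id, .data$module_id),
    "completeness.tsv")
  w(run$trophy |> arrange(.data$genome_id), "trophy.tsv")
  w(run$qualifying |> arrange(.data$sample_id), "qualifying.tsv")
  w(run$complementarity, "complementarity.tsv")
  w(run$run_manifest, "run_manifest.tsv")
  invisible(dir)
}
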