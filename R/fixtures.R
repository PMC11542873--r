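#' @title Deterministic study-scale fixtures
#'
#' @description
#' Three generators reproduce, in miniature or at printed scale, the tabular
#' structure of a published-style lichen metagenome collection. They are
#' deterministic (no RNG) and exist so that the arithmetic of the filtering
#' cascade, the frequency/share bookkeeping, and the trophy tabulations can
#' be exercised end to end at exactly the stage counts such a collection
#' presents.
#'
#' @name census-fixtures
NULL

#' Filtering-cascade fixture
#'
#' A manifest of `n_total` samples containing `n_duplicate_pairs` duplicated
#' deposits, `n_zero_mag` samples from which no MAG is recoverable,
#' `n_fungal` samples with a fungal MAG among those with any MAG,
#' `n_misassigned` samples whose declared lichen name contradicts their
#' fungal MAG's lineage, plus `n_reassigned` samples whose initial (deepest)
#' fungal candidate mismatches but a second present fungal MAG matches, and
#' `n_name_corrected` samples whose declared name is wrong but whose library
#' name resolves correctly. Defaults encode a 480-sample collection that
#' reduces to 437 after deduplication, 375 with at least one MAG (Dataset 1)
#' and 330 with a verified LFS (Dataset 2).
#'
#' @param n_total,n_duplicate_pairs,n_zero_mag,n_fungal,n_misassigned
#'   Stage counts (see above).
#' @param n_reassigned,n_name_corrected Resolved-inconsistency counts among
#'   the retained fungal-MAG samples.
#' @return A list with `manifest` (all samples), `duplicate_pairs`,
#'   `coverage`, `depths`, `taxonomy`, and `name_map` — ready for
#'   [deduplicate_samples()], [call_occurrence()], [assign_lfs()],
#'   [verify_lfs()], and [build_dataset_cascade()].
#' @export
simulate_cascade_fixture <- function(n_total = 480L, n_duplicate_pairs = 43L,
                                     n_zero_mag = 62L, n_fungal = 348L,
                                     n_misassigned = 18L, n_reassigned = 3L,
                                     n_name_corrected = 2L) {
  n_retained <- n_total - n_duplicate_pairs
  n_with_mag <- n_retained - n_zero_mag
  stopifnot(n_fungal <= n_with_mag,
            n_misassigned + n_reassigned + n_name_corrected <= n_fungal)
  ids <- sprintf("C%03d", seq_len(n_total))
  retained <- ids[seq_len(n_retained)]
  dup_ids <- ids[(n_retained + 1L):n_total]
  src_ids <- retained[seq_len(n_duplicate_pairs)]

  with_mag <- retained[seq_len(n_with_mag)]
  fungal_samples <- with_mag[seq_len(n_fungal)]
  bacterial_only <- setdiff(with_mag, fungal_samples)

  # status layout across the fungal-MAG samples:
  # [reassigned][name_corrected][verified ...][misassigned at the end]
  reassigned <- fungal_samples[seq_len(n_reassigned)]
  corrected <- fungal_samples[n_reassigned + seq_len(n_name_corrected)]
  misassigned <- fungal_samples[(n_fungal - n_misassigned + 1L):n_fungal]
  verified <- setdiff(fungal_samples, c(reassigned, corrected, misassigned))

  genus_pool <- c("Cladonia", "Peltigera", "Lecanora", "Umbilicaria",
                  "Rhizoplaca", "Evernia")
  genus_of <- setNames(
    genus_pool[((seq_along(fungal_samples) - 1L) %% length(genus_pool)) + 1L],
    fungal_samples
  )
  other_genus <- function(g) setdiff(genus_pool, g)[1L]

  fungal_mag <- sprintf("F_%s", fungal_samples)
  fungal_tax <- tibble(
    mag_id = fungal_mag,
    domain = "Fungi", phylum = "Ascomycota", class = "Lecanoromycetes",
    order = "Lecanorales",
    family = paste0(unname(genus_of[fungal_samples]), "ceae"),
    genus = unname(genus_of[fungal_samples]),
    species = paste(unname(genus_of[fungal_samples]), "sp")
  )
  # reassigned samples also carry a shallower fungal MAG of the declared genus
  alt_mag <- sprintf("Falt_%s", reassigned)
  alt_genus <- vapply(unname(genus_of[reassigned]), other_genus, character(1))
  alt_tax <- tibble(
    mag_id = alt_mag, domain = "Fungi", phylum = "Ascomycota",
    class = "Lecanoromycetes", order = "Lecanorales",
    family = paste0(alt_genus, "ceae"), genus = alt_genus,
    species = paste(alt_genus, "sp")
  )
  bact_tax <- tibble(
    mag_id = "B_shared", domain = "Bacteria", phylum = "Proteobacteria",
    class = "Alphaproteobacteria", order = "Hyphomicrobiales",
    family = "Beijerinckiaceae", genus = "Lichenihabitans",
    species = "Lichenihabitans sp"
  )
  taxonomy <- dplyr::bind_rows(fungal_tax, alt_tax, bact_tax)

  coverage <- dplyr::bind_rows(
    tibble(sample_id = fungal_samples, mag_id = fungal_mag,
           breadth = 0.92, depth = 30),
    tibble(sample_id = reassigned, mag_id = alt_mag,
           breadth = 0.80, depth = 5),
    tibble(sample_id = bacterial_only, mag_id = "B_shared",
           breadth = 0.85, depth = 12)
  )
  depths <- coverage |> select("sample_id", "mag_id", "depth")

  declared <- character(n_total)
  names(declared) <- ids
  library_name <- rep(NA_character_, n_total)
  names(library_name) <- ids
  declared[verified] <- paste(genus_of[verified], "verus")
  # reassigned: declared matches the alternative MAG, not the deep candidate
  declared[reassigned] <- paste(alt_genus, "alter")
  # name-corrected: declared name resolves to the wrong genus, the library
  # name to the right one
  declared[corrected] <- paste(
    vapply(unname(genus_of[corrected]), other_genus, character(1)), "verus")
  library_name[corrected] <- paste(genus_of[corrected], "verus")
  declared[misassigned] <- paste(
    vapply(unname(genus_of[misassigned]), other_genus, character(1)), "verus")
  declared[c(bacterial_only, retained[(n_with_mag + 1L):n_retained])] <-
    paste(genus_pool[1L], "verus")
  declared[dup_ids] <- declared[src_ids]

  manifest <- tibble(
    sample_id = ids,
    declared_lfs_name = unname(declared[ids]),
    library_name = unname(library_name[ids])
  )
  duplicate_pairs <- tibble(sample_a = src_ids, sample_b = dup_ids)

  name_map <- tibble(
    name = c(paste(genus_pool, "verus"), paste(genus_pool, "alter"),
             paste(genus_pool, "sp")),
    genus = rep(genus_pool, 3L)
  )

  list(manifest = manifest, duplicate_pairs = duplicate_pairs,
       coverage = coverage, depths = depths, taxonomy = taxonomy,
       name_map = name_map)
}

#' Run the filtering cascade on a cascade fixture
#'
#' Convenience wrapper chaining [deduplicate_samples()],
#' [call_occurrence()], [assign_lfs()], [verify_lfs()], and
#' [build_dataset_cascade()] on the output of
#' [simulate_cascade_fixture()].
#'
#' @param fixture Output of [simulate_cascade_fixture()].
#' @param breadth_min Presence threshold.
#' @return A `dataset_cascade` (with the deduplication result attached as
#'   attribute `dedup`).
#' @export
run_cascade_fixture <- function(fixture, breadth_min = 0.5) {
  dedup <- deduplicate_samples(fixture$manifest, fixture$duplicate_pairs)
  occ <- call_occurrence(fixture$coverage, breadth_min = breadth_min,
                         samples = dedup$manifest$sample_id)
  calls <- assign_lfs(occ, fixture$depths, fixture$taxonomy)
  calls <- verify_lfs(calls, dedup$manifest, fixture$name_map,
                      fixture$taxonomy, occ = occ, depths = fixture$depths)
  cascade <- build_dataset_cascade(dedup$manifest, occ, calls)
  attr(cascade, "dedup") <- dedup
  attr(cascade, "lfs_calls") <- calls
  cascade
}

# phylum composition of the species-level bacterial catalogue
census_phylum_counts <- c(
  Proteobacteria = 282L, Acidobacteriota = 153L, Actinobacteriota = 69L,
  Bacteroidota = 47L, Verrucomicrobiota = 29L, Cyanobacteria = 27L,
  Armatimonadota = 23L, Chloroflexota = 21L, Deinococcota = 6L,
  Eremiobacterota = 4L, Bdellovibrionota = 3L, Myxococcota = 3L,
  Patescibacteria = 3L, Planctomycetota = 2L, Chlamydiota = 1L,
  Firmicutes = 1L
)

# the 13 dominant genera: lineage count, occurrence count, family, phylum
census_top_genera <- function() tibble(
  genus = c("Lichenihabitans", "LMUY01", "CAHJXG01", "", "Lichenicoccus",
            "Lichenicola", "RH-AL1", "Sphingomonas", "Terriglobus",
            "Granulicella", "Acidipila", "Nostoc", "CAHJWO01"),
  family = c("Beijerinckiaceae", "Acetobacteraceae", "Acetobacteraceae",
             "Acetobacteraceae", "Acetobacteraceae", "Acetobacteraceae",
             "Beijerinckiaceae", "Sphingomonadaceae", "Acidobacteriaceae",
             "Acidobacteriaceae", "Acidobacteriaceae", "Nostocaceae",
             "UBA10450"),
  phylum = c("Proteobacteria", "Proteobacteria", "Proteobacteria",
             "Proteobacteria", "Proteobacteria", "Proteobacteria",
             "Proteobacteria", "Proteobacteria", "Acidobacteriota",
             "Acidobacteriota", "Acidobacteriota", "Cyanobacteria",
             "Verrucomicrobiota"),
  n_lineages = c(40L, 30L, 28L, 25L, 22L, 20L, 18L, 17L, 15L, 12L, 10L,
                 8L, 5L),
  n_occurrences = c(110L, 60L, 56L, 50L, 44L, 40L, 36L, 34L, 30L, 24L,
                    20L, 16L, 10L)
)

#' Bacterial census fixture
#'
#' A deterministic species-level occurrence matrix and taxonomy for a
#' bacterial MAG catalogue with the composition a continental-scale lichen
#' collection presents: 674 species-level lineages from 16 phyla (282
#' Proteobacteria, 153 Acidobacteriota, ...), 1,000 occurrences across 375
#' samples, with 13 dominant genera accounting for 250 lineages and 530
#' occurrences (including one genus-less Acetobacteraceae lineage group
#' exercising the `"<Family> gen. sp."` fallback). Occurrences are spread
#' over samples round-robin, so the fixture is RNG-free.
#'
#' @return A list with `occurrence` (a `lichen_occurrence`), `taxonomy`,
#'   `samples`, and `top_genera` (the planted dominant-genus table).
#' @export
simulate_census_fixture <- function() {
  top <- census_top_genera()
  # remaining lineages per phylum after the dominant genera are placed
  rest <- census_phylum_counts
  for (i in seq_len(nrow(top))) {
    rest[top$phylum[i]] <- rest[top$phylum[i]] - top$n_lineages[i]
  }
  stopifnot(all(rest >= 0))

  species <- list()
  k <- 0L
  add_species <- function(genus, family, phylum, n_lin, occ_counts) {
    k <<- k + n_lin
    tibble(
      mag_id = sprintf("sp%04d", (k - n_lin + 1L):k),
      phylum = phylum, family = family, genus = genus,
      occ = occ_counts
    )
  }
  # dominant genera: occurrences split across member lineages
  for (i in seq_len(nrow(top))) {
    n_lin <- top$n_lineages[i]
    occ_tot <- top$n_occurrences[i]
    base <- occ_tot %/% n_lin
    extra <- occ_tot %% n_lin
    occ_counts <- rep(base, n_lin) + c(rep(1L, extra), rep(0L, n_lin - extra))
    species[[length(species) + 1L]] <-
      add_species(top$genus[i], top$family[i], top$phylum[i], n_lin, occ_counts)
  }
  # remaining lineages: one per singleton genus; 46 of them occur twice so
  # the catalogue totals 1,000 occurrences
  rest_tbl <- purrr::imap(rest[rest > 0], function(n_lin, phylum) {
    tibble(phylum = phylum, idx = seq_len(n_lin))
  })
  rest_tbl <- dplyr::bind_rows(rest_tbl)
  occ_counts <- c(rep(2L, 46L), rep(1L, nrow(rest_tbl) - 46L))
  species[[length(species) + 1L]] <- add_species(
    genus = sprintf("Minorgenus%03d", seq_len(nrow(rest_tbl))),
    family = paste0(rest_tbl$phylum, "aceae"),
    phylum = rest_tbl$phylum, n_lin = nrow(rest_tbl), occ_counts = occ_counts
  )
  species <- dplyr::bind_rows(species)

  taxonomy <- species |>
    mutate(domain = "Bacteria", class = paste0(.data$phylum, "_c"),
           order = paste0(.data$family, "_o"),
           species = dplyr::if_else(nzchar(.data$genus),
                                    paste(.data$genus, "sp"),
                                    paste(.data$family, "sp"))) |>
    select("mag_id", "domain", "phylum", "class", "order", "family",
           "genus", "species")

  samples <- sprintf("D1_%03d", seq_len(375L))
  coverage <- purrr::map(seq_len(nrow(species)), function(j) {
    kk <- species$occ[j]
    idx <- ((j - 1L + seq_len(kk) - 1L) %% length(samples)) + 1L
    tibble(sample_id = samples[idx], mag_id = species$mag_id[j], breadth = 1)
  })
  coverage <- dplyr::bind_rows(coverage)
  occ <- call_occurrence(coverage, breadth_min = 0.5,
                         samples = samples, species = species$mag_id)
  list(occurrence = occ, taxonomy = taxonomy, samples = samples,
       top_genera = top)
}

#' Annotated-MAG trophy fixture
#'
#' KO tables for a set of near-complete bacterial MAGs with planted vitamin
#' statuses, defaulting to 63 genomes of which 27 are biotin prototrophs
#' (the share such an annotation set presents). Thiamine statuses cycle
#' through salvage-only, partial and auxotroph (no de novo thiamine
#' prototrophs, as observed in lichen bacteria); a minority are cobalamin
#' prototrophs. Planted statuses are retained for exact-recovery testing.
#'
#' @param n Number of genomes.
#' @param n_biotin_prototrophs How many are biotin prototrophs.
#' @param n_cobalamin_prototrophs How many are cobalamin prototrophs.
#' @return A list with `ko` (long KO table), `planted` (statuses per
#'   genome), `rules`, and `modules`.
#' @export
simulate_annotated_mags <- function(n = 63L, n_biotin_prototrophs = 27L,
                                    n_cobalamin_prototrophs = 6L) {
  stopifnot(n_biotin_prototrophs <= n, n_cobalamin_prototrophs <= n)
  rules <- synthetic_vitamin_rules()
  modules <- synthetic_module_library()
  ids <- sprintf("AB%03d", seq_len(n))
  biotin <- c(rep("prototroph", n_biotin_prototrophs),
              rep(c("partial", "auxotroph"),
                  length.out = n - n_biotin_prototrophs))
  thiamine <- rep(c("salvage_only", "partial", "auxotroph"), length.out = n)
  cobalamin <- c(rep("prototroph", n_cobalamin_prototrophs),
                 rep("auxotroph", n - n_cobalamin_prototrophs))
  planted <- tibble(genome_id = ids, biotin_status = biotin,
                    thiamine_status = thiamine, cobalamin_status = cobalamin)
  ko <- purrr::map(seq_len(n), function(i) {
    kos <- sort(unique(c(
      ko_for_status("biotin", biotin[i], rules, modules, variant = i),
      ko_for_status("thiamine", thiamine[i], rules, modules, variant = i),
      ko_for_status("cobalamin", cobalamin[i], rules, modules, variant = 1L)
    )))
    if (length(kos) == 0L) return(NULL)
    tibble(genome_id = ids[i], ko = kos)
  })
  list(ko = dplyr::bind_rows(ko), planted = planted, rules = rules,
       modules = modules)
}
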