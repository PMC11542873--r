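# small shared fixture: 3 samples x 4 species in two genera of one family
toy_occurrence <- function() {
  cov <- tibble::tibble(
    sample_id = c("s1", "s1", "s1", "s2", "s2", "s3", "s3", "s3"),
    mag_id = c("sp1", "sp2", "sp3", "sp1", "sp3", "sp1", "sp2", "sp4"),
    breadth = c(1, 1, 1, 1, 1, 1, 1, 0.2)
  )
  tax <- tibble::tibble(
    mag_id = c("sp1", "sp2", "sp3", "sp4"),
    domain = "Bacteria", phylum = "Proteobacteria",
    class = "Alphaproteobacteria", order = "Acetobacterales",
    family = "Acetobacteraceae",
    genus = c("GenA", "GenA", "GenB", ""),
    species = paste0("sp", 1:4)
  )
  list(occ = call_occurrence(cov), tax = tax)
}

test_that("frequency sums occurrences over member lineages with genus fallback", {
  fx <- toy_occurrence()
  freq <- tabulate_frequency(fx$occ, fx$tax, level = "genus")
  # GenA: sp1 occurs 3x, sp2 occurs 2x -> 5 occurrences over 2 lineages
  genA <- freq[freq$taxon == "GenA", ]
  expect_equal(genA$n_occurrences, 5L)
  expect_equal(genA$n_lineages, 2L)
  # sp4 never passes the threshold: its fallback group has no occurrence row
  expect_false("Acetobacteraceae gen. sp." %in% freq$taxon)
  # species-level occurrences within the family sum to the family count
  fam <- tabulate_frequency(fx$occ, fx$tax, level = "family")
  spc <- tabulate_frequency(fx$occ, fx$tax, level = "species")
  expect_equal(fam$n_occurrences[fam$taxon == "Acetobacteraceae"],
               sum(spc$n_occurrences))
  expect_error(tabulate_frequency(fx$occ, fx$tax, level = "cohort"),
               "unknown taxonomic level")
})

test_that("genus fallback labels genus-less lineages by family", {
  fx <- toy_occurrence()
  cov2 <- tibble::tibble(sample_id = "s1", mag_id = "sp4", breadth = 0.9)
  occ2 <- call_occurrence(cov2)
  freq <- tabulate_frequency(occ2, fx$tax, level = "genus")
  expect_identical(freq$taxon, "Acetobacteraceae gen. sp.")
})

test_that("the census fixture reproduces the catalogue-level shares", {
  cf <- simulate_census_fixture()
  fp <- tabulate_frequency(cf$occurrence, cf$taxonomy, level = "phylum")
  expect_equal(sum(fp$n_lineages), 674L)
  expect_equal(sum(fp$n_occurrences), 1000L)
  expect_equal(fp$n_lineages[fp$taxon == "Proteobacteria"], 282L)
  expect_equal(fp$n_lineages[fp$taxon == "Acidobacteriota"], 153L)
  expect_equal(pct_round(282, 674), 42L)
  expect_equal(pct_round(153, 674), 23L)
  fg <- tabulate_frequency(cf$occurrence, cf$taxonomy, level = "genus")
  sel <- rank_and_select_top(fg, 13)
  expect_equal(sum(sel$top$n_lineages), 250L)
  expect_equal(sel$lineage_share_pct, 37L)
  expect_equal(sel$occurrence_share_pct, 53L)
})

test_that("top-k selection is stable under ties and degenerate k", {
  freq <- tibble::tibble(
    taxon = c("Zeta", "Alpha", "Beta"), level = "genus",
    n_occurrences = c(5L, 5L, 2L), n_lineages = c(1L, 1L, 1L),
    n_samples = c(5L, 5L, 2L), prevalence_pct = 1L, denominator = 10L
  )
  sel <- rank_and_select_top(freq, 2)
  expect_identical(sel$top$taxon, c("Alpha", "Zeta")) # alphabetical tie-break
  expect_warning(all_sel <- rank_and_select_top(freq, 10), "exceeds")
  expect_equal(all_sel$lineage_share_pct, 100L)
  expect_error(rank_and_select_top(freq, 0), "k must be")
})

test_that("prevalence reproduces printed integer percentages from count pairs", {
  mk_detection <- function(n_detected, n_total, taxon) {
    tibble::tibble(
      sample_id = sprintf("p%03d", seq_len(n_total)),
      taxon = taxon,
      mag = FALSE,
      assembly_rrna = FALSE,
      read_rrna = seq_len(n_total) <= n_detected
    )
  }
  p1 <- prevalence(mk_detection(59, 278, "Ulvophyceae"), "Ulvophyceae",
                   tier = "read_rrna")
  expect_equal(p1$prevalence_pct, 21L)
  p2 <- prevalence(mk_detection(10, 23, "Ulvophyceae"), "Ulvophyceae",
                   tier = "read_rrna")
  expect_equal(p2$prevalence_pct, 43L)
  expect_equal(pct_round(62, 437), 14L)
  expect_error(prevalence(mk_detection(1, 5, "X"), "X", subset = character()),
               "empty")
  # invariant to row permutation
  det <- mk_detection(7, 20, "T")
  expect_identical(prevalence(det, "T", tier = "read_rrna"),
                   prevalence(det[sample(20), ], "T", tier = "read_rrna"))
})

test_that("detection tiers merge without cross-tier inference and roll up ranks", {
  fx <- toy_occurrence()
  rrna <- tibble::tibble(
    sample_id = c("s2", "s3"),
    mag_id = c("sp2", "sp4"),
    tier = c("read", "read"),
    detected = TRUE
  )
  det <- merge_detection_tiers(fx$occ, rrna, fx$tax, level = "genus")
  g <- function(s, t) det[det$sample_id == s & det$taxon == t, ]
  # MAG present, rRNA absent stays (1,0,0)
  row <- g("s1", "GenA")
  expect_true(row$mag); expect_false(row$assembly_rrna); expect_false(row$read_rrna)
  # rRNA detection of sp4 rolls up to its fallback genus, MAG tier untouched
  row2 <- g("s3", "Acetobacteraceae gen. sp.")
  expect_false(row2$mag); expect_true(row2$read_rrna)
  # species-level MAG occurrence rolls up to the family tier
  det_fam <- merge_detection_tiers(fx$occ, rrna, fx$tax, level = "family")
  expect_true(all(det_fam$mag[det_fam$taxon == "Acetobacteraceae" &
                                det_fam$sample_id %in% c("s1", "s2", "s3")]))
  # empty rRNA table: rRNA tiers all false
  det0 <- merge_detection_tiers(fx$occ, NULL, fx$tax, level = "genus")
  expect_false(any(det0$assembly_rrna) || any(det0$read_rrna))
  # an organism missing from the taxonomy is an error
  expect_error(
    merge_detection_tiers(fx$occ, tibble::tibble(sample_id = "s1",
                                                 mag_id = "mystery",
                                                 tier = "read",
                                                 detected = TRUE),
                          fx$tax),
    "absent from taxonomy")
})

test_that("roll-up consistency: detection at species implies every ancestor rank", {
  b <- generate_bundle(simulation_config(seed = 31, n_samples = 30))
  occ <- call_occurrence(b$coverage, samples = b$manifest$sample_id,
                         species = b$organisms$organism_id)
  for (level in c("genus", "family", "class", "phylum")) {
    det <- merge_detection_tiers(occ, b$rrna, b$taxonomy, level = level)
    labels <- setNames(
      if (level == "genus") {
        ifelse(nzchar(b$taxonomy$genus), b$taxonomy$genus,
               paste(b$taxonomy$family, "gen. sp."))
      } else {
        b$taxonomy[[level]]
      },
      b$taxonomy$mag_id
    )
    pres <- as.data.frame(occ[occ$present, c("sample_id", "mag_id")])
    for (i in seq_len(nrow(pres))) {
      hit <- det[det$sample_id == pres$sample_id[i] &
                   det$taxon == labels[pres$mag_id[i]], ]
      expect_true(hit$mag)
    }
  }
})

test_that("screening outcomes classify and order by depth", {
  det <- tibble::tibble(
    sample_id = c("a", "b", "c", "d"),
    taxon = "T",
    mag = c(TRUE, TRUE, FALSE, FALSE),
    assembly_rrna = c(TRUE, FALSE, FALSE, FALSE),
    read_rrna = c(TRUE, FALSE, TRUE, FALSE)
  )
  out <- classify_detection_outcome(det)
  expect_identical(as.character(out$outcome),
                   c("mag_and_rrna", "mag_only", "rrna_only", "not_detected"))
  depths <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                           total_depth_bp = c(1e9, 5e9, 1e8, 2e10))
  out2 <- classify_detection_outcome(det, depths)
  expect_identical(out2$sample_id, c("a", "b", "c", "d")) # outcome order first
})

test_that("rRNA-only detections concentrate at low depth, monotone over deciles", {
  # alga-like organism (multicopy rDNA, strain-mixed) over a depth range
  # between the rRNA detection floor and well past the recovery transition
  withr::with_seed(59, {
    n <- 2000
    total <- 10^runif(n, 7, log10(3e10))
    depth <- depth_for_organism(total, 0.1, 5e7)
    det <- rrna_detected(depth, rrna_copies = 100, rrna_length = 1800,
                         read_length = 150, strain_multiplicity = 2)
    mag <- breadth_from_depth(depth, 2) >= 0.5
    rrna_only <- det$read_tier & !mag
    decile <- cut(rank(total, ties.method = "first"),
                  breaks = 10, labels = FALSE)
    frac <- tapply(rrna_only, decile, mean)
    expect_true(all(diff(frac) <= 0))
    expect_gt(frac[1], frac[10])
  })
})

test_that("co-occurrence networks count shared samples exactly", {
  fx <- toy_occurrence()
  net <- build_cooccurrence(fx$occ)
  # brute-force oracle over all pairs
  m <- occurrence_matrix(fx$occ)
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$lineage_a[i]; b <- net$edges$lineage_b[i]
    expect_equal(net$edges$weight[i], sum(m[, a] & m[, b]))
  }
  # sp1 & sp3 share s1 and s2
  e13 <- net$edges[net$edges$lineage_a == "sp1" & net$edges$lineage_b == "sp3", ]
  expect_equal(e13$weight, 2L)
  # zero-weight pairs and never-present lineages are omitted
  expect_false("sp4" %in% net$nodes$lineage)
  expect_true(all(net$edges$weight >= 1))
  expect_true(all(net$edges$lineage_a < net$edges$lineage_b))
})

test_that("an explicit edge-weight example and node classes survive", {
  pres <- tibble::tibble(
    sample_id = rep(sprintf("s%d", 1:5), each = 2),
    lineage = rep(c("L1", "L2"), 5)
  )
  classes <- tibble::tibble(lineage = c("L1", "L2"), class = c("LFS", "alga"))
  net <- build_cooccurrence(pres, node_classes = classes)
  expect_equal(net$edges$weight, 5L)
  expect_identical(net$nodes$class, c("LFS", "alga"))
  g <- as_igraph(net)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::vcount(g), 2)
})

test_that("read-tier prevalence dominates MAG-tier prevalence on simulated data", {
  b <- generate_bundle(simulation_config(seed = 13, n_samples = 60))
  occ <- call_occurrence(b$coverage, samples = b$manifest$sample_id,
                         species = b$organisms$organism_id)
  det <- merge_detection_tiers(occ, b$rrna, b$taxonomy, level = "genus")
  # genera whose genomes lack rRNA annotations cannot be screened and are
  # excluded from the tier comparison, as in real rRNA screening
  screenable <- b$taxonomy |>
    dplyr::left_join(b$organisms[, c("organism_id", "rrna_copies")],
                     by = c(mag_id = "organism_id")) |>
    dplyr::group_by(.data$genus) |>
    dplyr::summarise(ok = all(.data$rrna_copies >= 1)) |>
    dplyr::filter(.data$ok) |>
    dplyr::pull("genus")
  for (tx in intersect(unique(det$taxon), screenable)) {
    p_read <- prevalence(det, tx, tier = "read_rrna")$n_detected
    p_mag <- prevalence(det, tx, tier = "mag")$n_detected
    expect_gte(p_read, p_mag)
  }
  expect_gt(length(intersect(unique(det$taxon), screenable)), 5)
})
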