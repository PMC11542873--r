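#' @title Synthetic lichen-metagenome communities
#'
#' @description
#' The simulator emits the full set of input tables the census pipeline
#' consumes (coverage, quality, taxonomy, KO annotations, rRNA screening,
#' manifest, ANI, ground truth), with the statistical structure real lichen
#' metagenome collections exhibit: organism-specific genome sizes and
#' cellular abundances, strain multiplicity penalizing assembly, multicopy
#' rRNA markers detectable far below genome-recovery depth, sequencing
#' depths spanning six orders of magnitude, duplicated library deposits,
#' and occasional misidentified samples. Ground truth is retained so that
#' pipeline recovery can be tested exactly.
#'
#' @name synthetic-community
NULL

#' Expected per-base depth of one organism in one sample
#'
#' The sequencing effort an organism receives is proportional to its share
#' of the sample's DNA: `depth = total_depth_bp * mass_fraction /
#' genome_size`.
#'
#' @param total_depth_bp Total sequenced base pairs of the sample.
#' @param mass_fraction The organism's fraction of total sample DNA, in
#'   \[0, 1\].
#' @param genome_size Genome size in bp; must be positive.
#' @return Expected per-base depth(s) of coverage.
#' @examples
#' depth_for_organism(1e9, 0.05, 50e6) # 1.0
#' @export
depth_for_organism <- function(total_depth_bp, mass_fraction, genome_size) {
  if (any(genome_size <= 0)) abort("depth_for_organism(): genome_size must be positive")
  if (any(mass_fraction < 0 | mass_fraction > 1)) {
    abort("depth_for_organism(): mass_fraction must lie in [0, 1]")
  }
  if (any(total_depth_bp <= 0)) abort("depth_for_organism(): total_depth_bp must be positive")
  total_depth_bp * mass_fraction / genome_size
}

#' Breadth of coverage under the Lander-Waterman model
#'
#' The expected fraction of genome positions covered by at least one read at
#' per-base depth `c` is `1 - exp(-c)`. Strain mixtures and polyploidy break
#' assemblies and fragment read recruitment; this is modelled by dividing
#' the effective depth by `strain_multiplicity^penalty` before applying the
#' Lander-Waterman expectation. The functional form of the penalty is
#' illustrative (no quantitative model of strain-mixture effects exists);
#' the exponent is configurable and defaults to 1.
#'
#' @param depth Per-base depth(s) of coverage, >= 0.
#' @param strain_multiplicity Number of co-occurring strains/haplotypes,
#'   >= 1.
#' @param penalty Non-negative exponent on the multiplicity divisor.
#' @return Breadth fraction(s) in \[0, 1\]; monotone non-decreasing in depth
#'   and non-increasing in multiplicity.
#' @examples
#' breadth_from_depth(log(2)) # exactly 0.5
#' @export
breadth_from_depth <- function(depth, strain_multiplicity = 1, penalty = 1) {
  if (any(depth < 0)) abort("breadth_from_depth(): depth must be >= 0")
  if (any(strain_multiplicity < 1)) {
    abort("breadth_from_depth(): strain_multiplicity must be >= 1")
  }
  if (any(penalty < 0)) abort("breadth_from_depth(): penalty must be >= 0")
  1 - exp(-depth / strain_multiplicity^penalty)
}

#' Expected number of reads overlapping the rRNA loci
#'
#' With `n = depth * genome_size / read_length` reads placed on the genome,
#' the expected number overlapping any of `rrna_copies` loci of length
#' `rrna_length` is `n * rrna_copies * (rrna_length + read_length - 1) /
#' genome_size`; the genome size cancels, leaving
#' `depth * rrna_copies * (rrna_length + read_length - 1) / read_length`.
#'
#' @inheritParams breadth_from_depth
#' @param rrna_copies rRNA operon/rDNA copy number, >= 0.
#' @param rrna_length SSU rRNA gene length in bp.
#' @param read_length Read length in bp.
#' @return Expected overlapping read count(s).
#' @export
rrna_read_lambda <- function(depth, rrna_copies, rrna_length, read_length) {
  depth * rrna_copies * (rrna_length + read_length - 1) / read_length
}

#' Simulate SSU rRNA detection on the read and assembly tiers
#'
#' Read-tier detection occurs when a Poisson draw with mean
#' [rrna_read_lambda()] reaches `min_reads`, or when the organism's genome
#' itself passes the breadth-based recovery gate (a genome covered broadly
#' enough to be recovered as a MAG necessarily has reads over its multicopy
#' rRNA loci; the Poisson term matters in the shallow regime). Assembly-tier
#' detection additionally requires an effective depth of at least 1 (a proxy
#' for assemblability), so assembly-tier detection always implies read-tier
#' detection, and read-tier detection probability is at least the MAG
#' recovery probability at every depth — the detectability ordering observed
#' between raw-read screening, assembly screening, and MAG recovery.
#' Organisms with zero rRNA copies are never detected on either tier.
#'
#' Draws use the current RNG state; callers seed it.
#'
#' @inheritParams rrna_read_lambda
#' @inheritParams breadth_from_depth
#' @param min_reads Reads required for a read-tier detection, >= 1.
#' @param breadth_threshold Breadth gate shared with MAG presence calling.
#' @return A tibble with logical columns `read_tier` and `assembly_tier`,
#'   one row per input element.
#' @export
rrna_detected <- function(depth, rrna_copies, rrna_length, read_length,
                          min_reads = 1, strain_multiplicity = 1, penalty = 1,
                          breadth_threshold = 0.5) {
  if (any(min_reads < 1)) abort("rrna_detected(): min_reads must be >= 1")
  if (any(rrna_copies < 0)) abort("rrna_detected(): rrna_copies must be >= 0")
  n <- max(length(depth), length(rrna_copies))
  lambda <- rrna_read_lambda(depth, rrna_copies, rrna_length, read_length)
  draws <- rpois(n, lambda)
  breadth <- breadth_from_depth(depth, strain_multiplicity, penalty)
  effective <- depth / strain_multiplicity^penalty
  read_tier <- rrna_copies >= 1 &
    (draws >= min_reads | breadth >= breadth_threshold)
  assembly_tier <- read_tier & effective >= 1
  tibble(read_tier = read_tier, assembly_tier = assembly_tier)
}

#' Simulation configuration
#'
#' Study conditions for the synthetic community: sample count, the
#' log-uniform sequencing-depth range (six orders of magnitude, matching the
#' span of published lichen metagenomes), read length, the strain penalty
#' exponent, rRNA detection threshold, the presence-calling breadth
#' threshold, and the numbers of duplicated and misidentified samples.
#'
#' @param seed Integer seed; identical configurations yield byte-identical
#'   bundles.
#' @param n_samples Number of metagenome samples.
#' @param depth_range Min/max total sequencing depth in bp, sampled
#'   log-uniformly.
#' @param read_length Read length in bp.
#' @param strain_penalty Exponent of the strain-multiplicity divisor.
#' @param min_rrna_reads Reads required for read-tier rRNA detection.
#' @param breadth_threshold Presence-calling breadth threshold.
#' @param n_duplicate_pairs Samples deposited twice (byte-identical rows).
#' @param n_misidentified Samples whose declared lichen name contradicts
#'   their actual fungal symbiont.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_samples = 100L,
                              depth_range = c(1e6, 1e12),
                              read_length = 150L,
                              strain_penalty = 1,
                              min_rrna_reads = 1L,
                              breadth_threshold = 0.5,
                              n_duplicate_pairs = 5L,
                              n_misidentified = 3L) {
  stopifnot(length(depth_range) == 2L, depth_range[1] > 0,
            depth_range[2] > depth_range[1],
            n_samples >= 1, min_rrna_reads >= 1, strain_penalty >= 0,
            breadth_threshold > 0, breadth_threshold <= 1,
            n_duplicate_pairs >= 0, n_misidentified >= 0,
            n_duplicate_pairs + n_misidentified <= n_samples)
  structure(list(
    seed = as.integer(seed), n_samples = as.integer(n_samples),
    depth_range = depth_range, read_length = as.integer(read_length),
    strain_penalty = strain_penalty, min_rrna_reads = as.integer(min_rrna_reads),
    breadth_threshold = breadth_threshold,
    n_duplicate_pairs = as.integer(n_duplicate_pairs),
    n_misidentified = as.integer(n_misidentified)
  ), class = "simulation_config")
}

# ---- synthetic KEGG content ------------------------------------------------

#' Synthetic KEGG-style module definitions and vitamin rules
#'
#' Structurally realistic but entirely synthetic module definitions (KO
#' identifiers in the K90xxx range, which real KEGG does not use) standing
#' in for the vitamin-pathway modules the trophy rules reference: biotin
#' ring assembly (M00123 with an alternative M00950), thiamine synthesis
#' (M00127) and salvage (M00899, plus the thiMDE three-gene route), and
#' cobalamin synthesis (prokaryotic M00122, eukaryotic M00925). Real KEGG
#' definition content is licensed and is not shipped; analyses of real
#' annotations must supply their own definitions table.
#'
#' @return `synthetic_module_library()`: a tibble `module_id`, `name`,
#'   `definition`.
#' @export
synthetic_module_library <- function() {
  tibble(
    module_id = c("M00123", "M00950", "M00127", "M00899", "M00122", "M00925"),
    name = c(
      "biotin ring assembly (synthetic stand-in)",
      "biotin ring assembly, alternative route (synthetic stand-in)",
      "thiamine de novo synthesis (synthetic stand-in)",
      "thiamine salvage (synthetic stand-in)",
      "cobalamin synthesis, prokaryotic (synthetic stand-in)",
      "cobalamin synthesis, eukaryotic (synthetic stand-in)"
    ),
    definition = c(
      "K90101 (K90102,K90103) K90104 K90105+K90106",
      "K90111 K90112 (K90113,K90114)",
      "K90221 K90222 K90223 K90224",
      "K90201 K90202 (K90203,K90204)",
      "K90301 K90302 K90303 K90304",
      "K90311 K90312+K90313 K90314"
    )
  )
}

#' @rdname synthetic_module_library
#' @return `synthetic_vitamin_rules()`: a [vitamin_rules()] object wired to
#'   the synthetic module library, with thiMDE as a named three-KO
#'   conjunction alternative for thiamine salvage and synthetic metE/metH
#'   marker KOs.
#' @export
synthetic_vitamin_rules <- function() {
  vitamin_rules(
    vitamins = list(
      biotin = list(synthesis_modules = c("M00123", "M00950")),
      thiamine = list(
        synthesis_modules = "M00127",
        salvage_modules = "M00899",
        salvage_gene_sets = list(thiMDE = c("K90211", "K90212", "K90213"))
      ),
      cobalamin = list(synthesis_modules = c("M00122", "M00925"))
    ),
    genes = list(metE = "K90401", metH = "K90402")
  )
}

#' KO set realizing a planted trophy status
#'
#' Builds, from the rule set and module definitions, a KO set that an
#' organism planted with the given status must carry: prototrophs get every
#' KO of one synthesis route, salvagers every KO of one salvage route,
#' partial organisms only the first block of a synthesis route, auxotrophs
#' nothing. Used by the simulator so that planted statuses are exactly
#' recoverable by [classify_trophy()].
#'
#' @param vitamin Vitamin name present in the rules.
#' @param status One of `prototroph`, `salvage_only`, `partial`,
#'   `auxotroph`.
#' @param rules A [vitamin_rules()] object.
#' @param modules Module definitions tibble.
#' @param variant 1-based index cycling over alternative routes.
#' @return Character vector of KO identifiers (possibly empty).
#' @export
ko_for_status <- function(vitamin, status, rules = synthetic_vitamin_rules(),
                          modules = synthetic_module_library(), variant = 1L) {
  stopifnot(inherits(rules, "vitamin_rules"), vitamin %in% names(rules$vitamins))
  rule <- rules$vitamins[[vitamin]]
  parsed <- parse_rule_modules(rules, modules)
  pick <- function(routes, k) routes[[(k - 1L) %% length(routes) + 1L]]
  synth_routes <- c(as.list(rule$synthesis_modules %||% character()),
                    unname(rule$synthesis_gene_sets %||% list()))
  salv_routes <- c(as.list(rule$salvage_modules %||% character()),
                   unname(rule$salvage_gene_sets %||% list()))
  route_kos <- function(route) {
    if (is.character(route) && length(route) == 1L && grepl("^M\\d{5}$", route)) {
      module_kos(parsed[[route]])
    } else {
      route
    }
  }
  switch(status,
    prototroph = route_kos(pick(synth_routes, variant)),
    salvage_only = {
      if (length(salv_routes) == 0L) {
        abort(sprintf("no salvage route defined for vitamin '%s'", vitamin))
      }
      route_kos(pick(salv_routes, variant))
    },
    partial = {
      route <- pick(synth_routes, variant)
      if (is.character(route) && length(route) == 1L && grepl("^M\\d{5}$", route)) {
        module_kos(module_blocks(parsed[[route]])[[1L]])
      } else {
        route[1L]
      }
    },
    auxotroph = character(),
    abort(sprintf("unknown trophy status '%s'", status))
  )
}

# ---- organism roster -------------------------------------------------------

lfs_genera <- c("Cladonia", "Peltigera", "Lecanora", "Umbilicaria",
                "Rhizoplaca", "Evernia", "Letharia", "Alectoria",
                "Bryoria", "Usnea")

lichen_lineage <- function(domain, phylum, class, order, family, genus, species) {
  paste(domain, phylum, class, order, family, genus, species, sep = ";")
}

# the fixed non-fungal organism pool shared across samples
base_organism_pool <- function() {
  tibble(
    organism_id = c(
      "alga_Trebouxia_sp1", "alga_Trebouxia_sp2", "cyano_Nostoc_sp1",
      "yeast_Cystobasidium_sp1", "yeast_Tremella_sp1",
      "bact_Lichenihabitans_sp1", "bact_Lichenihabitans_sp2",
      "bact_RHAL1_sp1", "bact_LMUY01_sp1", "bact_CAHJXG01_sp1",
      "bact_Lichenicoccus_sp1", "bact_Lichenicola_sp1",
      "bact_Terriglobus_sp1", "bact_Granulicella_sp1",
      "bact_Sphingomonas_sp1", "bact_Sphingomonas_sp2",
      "bact_CAHJWO01_sp1"
    ),
    role = c("alga", "alga", "cyanobacterium", "yeast", "yeast",
             rep("bacterium", 12L)),
    lineage = c(
      lichen_lineage("Algae", "Chlorophyta", "Trebouxiophyceae", "Trebouxiales",
                     "Trebouxiaceae", "Trebouxia", "Trebouxia sp1"),
      lichen_lineage("Algae", "Chlorophyta", "Trebouxiophyceae", "Trebouxiales",
                     "Trebouxiaceae", "Trebouxia", "Trebouxia sp2"),
      lichen_lineage("Bacteria", "Cyanobacteria", "Cyanophyceae", "Nostocales",
                     "Nostocaceae", "Nostoc", "Nostoc sp1"),
      lichen_lineage("Fungi", "Basidiomycota", "Cystobasidiomycetes",
                     "Cystobasidiales", "Cystobasidiaceae", "Cystobasidium",
                     "Cystobasidium sp1"),
      lichen_lineage("Fungi", "Basidiomycota", "Tremellomycetes", "Tremellales",
                     "Tremellaceae", "Tremella", "Tremella sp1"),
      lichen_lineage("Bacteria", "Proteobacteria", "Alphaproteobacteria",
                     "Hyphomicrobiales", "Beijerinckiaceae", "Lichenihabitans",
                     "Lichenihabitans sp1"),
      lichen_lineage("Bacteria", "Proteobacteria", "Alphaproteobacteria",
                     "Hyphomicrobiales", "Beijerinckiaceae", "Lichenihabitans",
                     "Lichenihabitans sp2"),
      lichen_lineage("Bacteria", "Proteobacteria", "Alphaproteobacteria",
                     "Hyphomicrobiales", "Beijerinckiaceae", "RH-AL1",
                     "RH-AL1 sp1"),
      lichen_lineage("Bacteria", "Proteobacteria", "Alphaproteobacteria",
                     "Acetobacterales", "Acetobacteraceae", "LMUY01",
                     "LMUY01 sp1"),
      lichen_lineage("Bacteria", "Proteobacteria", "Alphaproteobacteria",
                     "Acetobacterales", "Acetobacteraceae", "CAHJXG01",
                     "CAHJXG01 sp1"),
      lichen_lineage("Bacteria", "Proteobacteria", "Alphaproteobacteria",
                     "Acetobacterales", "Acetobacteraceae", "Lichenicoccus",
                     "Lichenicoccus sp1"),
      lichen_lineage("Bacteria", "Proteobacteria", "Alphaproteobacteria",
                     "Acetobacterales", "Acetobacteraceae", "Lichenicola",
                     "Lichenicola sp1"),
      lichen_lineage("Bacteria", "Acidobacteriota", "Acidobacteriae",
                     "Acidobacteriales", "Acidobacteriaceae", "Terriglobus",
                     "Terriglobus sp1"),
      lichen_lineage("Bacteria", "Acidobacteriota", "Acidobacteriae",
                     "Acidobacteriales", "Acidobacteriaceae", "Granulicella",
                     "Granulicella sp1"),
      lichen_lineage("Bacteria", "Proteobacteria", "Alphaproteobacteria",
                     "Sphingomonadales", "Sphingomonadaceae", "Sphingomonas",
                     "Sphingomonas sp1"),
      lichen_lineage("Bacteria", "Proteobacteria", "Alphaproteobacteria",
                     "Sphingomonadales", "Sphingomonadaceae", "Sphingomonas",
                     "Sphingomonas sp2"),
      lichen_lineage("Bacteria", "Verrucomicrobiota", "Verrucomicrobiae",
                     "Chthoniobacterales", "UBA10450", "CAHJWO01",
                     "CAHJWO01 sp1")
    ),
    genome_size = c(55e6, 60e6, 7e6, 20e6, 22e6,
                    4.5e6, 4.7e6, 4.2e6, 5.5e6, 5.2e6, 5.0e6, 4.8e6,
                    5.8e6, 5.6e6, 4.0e6, 4.1e6, 6.2e6),
    rrna_copies = c(300, 300, 4, 60, 60,
                    2, 2, 2, 3, 0, 3, 3, 2, 2, 3, 3, 0),
    rrna_length = c(1800, 1800, 1500, 1800, 1800, rep(1550, 12L)),
    strain_multiplicity = c(2, 2, 1, 1, 1, rep(1, 12L)),
    base_prevalence = c(0.55, 0.30, 0.30, 0.50, 0.35,
                        0.70, 0.35, 0.30, 0.55, 0.50, 0.40, 0.35,
                        0.45, 0.35, 0.40, 0.25, 0.30),
    mass_lo = c(0.05, 0.03, 0.02, NA, NA,
                rep(0.001, 12L)),
    mass_hi = c(0.15, 0.10, 0.10, NA, NA,
                rep(0.03, 12L)),
    biotin_status = c("partial", "prototroph", "prototroph", "partial", "partial",
                      "prototroph", "auxotroph", "prototroph", "prototroph",
                      "auxotroph", "prototroph", "auxotroph", "partial",
                      "auxotroph", "partial", "auxotroph", "auxotroph"),
    thiamine_status = c("prototroph", "salvage_only", "partial", "salvage_only",
                        "salvage_only",
                        "salvage_only", "auxotroph", "salvage_only", "salvage_only",
                        "auxotroph", "partial", "auxotroph", "partial",
                        "auxotroph", "salvage_only", "auxotroph", "auxotroph"),
    cobalamin_status = c("partial", "partial", "prototroph", "auxotroph",
                         "auxotroph",
                         "auxotroph", "auxotroph", "auxotroph", "prototroph",
                         "auxotroph", "prototroph", "auxotroph", "auxotroph",
                         "auxotroph", "prototroph", "auxotroph", "auxotroph"),
    metE = c(TRUE, TRUE, FALSE, FALSE, FALSE, rep(FALSE, 12L)),
    metH = c(TRUE, FALSE, TRUE, FALSE, FALSE, rep(FALSE, 12L))
  )
}

lfs_organism_pool <- function(n_species) {
  genus <- lfs_genera[((seq_len(n_species) - 1L) %% length(lfs_genera)) + 1L]
  idx <- stats::ave(seq_len(n_species), genus, FUN = seq_along)
  species <- sprintf("%s sp%d", genus, idx)
  tibble(
    organism_id = sprintf("lfs_%s_sp%d", genus, idx),
    role = "LFS",
    lineage = lichen_lineage("Fungi", "Ascomycota", "Lecanoromycetes",
                             "Lecanorales", paste0(genus, "ceae"),
                             genus, species),
    genome_size = 35e6,
    rrna_copies = 60,
    rrna_length = 1800,
    strain_multiplicity = 1,
    base_prevalence = NA_real_,
    mass_lo = NA_real_, mass_hi = NA_real_,
    biotin_status = "auxotroph",
    thiamine_status = rep(c("salvage_only", "partial", "auxotroph"),
                          length.out = n_species),
    cobalamin_status = "auxotroph",
    metE = FALSE, metH = FALSE
  )
}

#' Simulate a lichen community roster
#'
#' Draws the organism roster and per-sample membership under the study
#' conditions in the configuration: one LFS per sample (drawn from a pool of
#' lecanoromycete species so that some samples share an LFS), widely shared
#' photobionts (a strain-mixed *Trebouxia* alga, a single-strain *Nostoc*),
#' basidiomycete yeasts at the ~1:100 abundance regime, and a pool of
#' bacteria from the high-frequency lichen families. Sample depths are drawn
#' log-uniformly over the configured range. The last `n_duplicate_pairs`
#' samples are duplicates of the first ones; `n_misidentified` samples get a
#' declared lichen name inconsistent with their actual LFS.
#'
#' @param config A [simulation_config()].
#' @return A `lichen_community`: list with `organisms` (roster with planted
#'   trophy statuses), `membership` (`sample_id`, `organism_id`,
#'   `mass_fraction`), `manifest`, `name_map`, and `duplicate_pairs`.
#' @export
simulate_community <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_samples
  n_dup <- config$n_duplicate_pairs
  n_orig <- n - n_dup
  if (n_orig < 1L) abort("simulate_community(): need at least one non-duplicate sample")

  n_lfs <- max(3L, min(n_orig, 30L))
  lfs_pool <- lfs_organism_pool(n_lfs)
  pool <- base_organism_pool()
  organisms <- dplyr::bind_rows(lfs_pool, pool)
  if (anyDuplicated(organisms$organism_id)) {
    abort("simulate_community(): conflicting organism ids in roster")
  }

  sample_ids <- sprintf("S%04d", seq_len(n))
  orig_ids <- sample_ids[seq_len(n_orig)]

  # per-sample membership for the original (non-duplicate) samples
  membership <- purrr::map(seq_len(n_orig), function(i) {
    lfs <- lfs_pool$organism_id[((i - 1L) %% n_lfs) + 1L]
    lfs_mass <- runif(1, 0.45, 0.70)
    picked <- pool |>
      mutate(u = runif(dplyr::n())) |>
      filter(.data$u < .data$base_prevalence)
    mass <- runif(nrow(picked),
                  dplyr::coalesce(picked$mass_lo, 0),
                  dplyr::coalesce(picked$mass_hi, 1))
    # yeasts sit at the ~1:100 coverage regime relative to the LFS
    mass[picked$role == "yeast"] <- lfs_mass / 100
    rows <- tibble(
      sample_id = orig_ids[i],
      organism_id = c(lfs, picked$organism_id),
      mass_fraction = c(lfs_mass, mass)
    )
    total <- sum(rows$mass_fraction)
    if (total > 0.98) rows$mass_fraction <- rows$mass_fraction * 0.98 / total
    rows
  })
  membership <- dplyr::bind_rows(membership)

  depths <- 10^runif(n_orig, log10(config$depth_range[1]),
                     log10(config$depth_range[2]))

  # declared names resolve to the LFS genus via the name map
  lfs_of_sample <- membership |>
    inner_join(organisms |> filter(.data$role == "LFS") |>
                 select("organism_id", "lineage"),
               by = "organism_id")
  lfs_tax <- parse_lineage(lfs_of_sample$organism_id, lfs_of_sample$lineage)
  declared <- setNames(
    paste(lfs_tax$genus, sub("^.* ", "", lfs_tax$species)),
    lfs_of_sample$sample_id
  )
  declared_genus <- setNames(lfs_tax$genus, lfs_of_sample$sample_id)

  manifest <- tibble(
    sample_id = orig_ids,
    declared_lfs_name = unname(declared[orig_ids]),
    library_name = NA_character_,
    total_depth_bp = depths,
    read_length = config$read_length,
    duplicate_of = NA_character_,
    misidentified = FALSE
  )

  # misidentify: swap the declared name to a different genus
  if (config$n_misidentified > 0L) {
    mis_idx <- sample(n_orig, config$n_misidentified)
    for (i in mis_idx) {
      own <- declared_genus[manifest$sample_id[i]]
      other <- setdiff(lfs_genera, own)[1L]
      manifest$declared_lfs_name[i] <- paste(other, "sp1")
      manifest$misidentified[i] <- TRUE
    }
  }

  # duplicates of the first n_dup originals: same membership, name, depth
  duplicate_pairs <- tibble(sample_a = character(), sample_b = character())
  if (n_dup > 0L) {
    dup_ids <- sample_ids[(n_orig + 1L):n]
    src_ids <- orig_ids[seq_len(n_dup)]
    dup_manifest <- manifest[match(src_ids, manifest$sample_id), ] |>
      mutate(sample_id = dup_ids, duplicate_of = src_ids)
    manifest <- dplyr::bind_rows(manifest, dup_manifest)
    dup_membership <- membership |>
      filter(.data$sample_id %in% src_ids) |>
      mutate(sample_id = dup_ids[match(.data$sample_id, src_ids)])
    membership <- dplyr::bind_rows(membership, dup_membership)
    duplicate_pairs <- tibble(sample_a = src_ids, sample_b = dup_ids)
  }

  # the name map resolves every (species-level) declared name to its genus
  name_map <- tibble(
    name = sprintf("%s sp%d", rep(lfs_genera, each = 5L), rep(1:5, length(lfs_genera)))
  ) |>
    mutate(genus = sub(" .*$", "", .data$name))

  structure(
    list(organisms = organisms, membership = membership, manifest = manifest,
         name_map = name_map, duplicate_pairs = duplicate_pairs,
         config = config),
    class = "lichen_community"
  )
}

# KO set of one organism from its planted statuses + marker genes
planted_ko_set <- function(org, rules, modules) {
  kos <- c(
    ko_for_status("biotin", org$biotin_status, rules, modules,
                  variant = org$variant),
    ko_for_status("thiamine", org$thiamine_status, rules, modules,
                  variant = org$variant),
    ko_for_status("cobalamin", org$cobalamin_status, rules, modules,
                  variant = org$variant)
  )
  if (isTRUE(org$metE)) kos <- c(kos, rules$genes$metE)
  if (isTRUE(org$metH)) kos <- c(kos, rules$genes$metH)
  sort(unique(kos))
}

#' Generate the full synthetic input bundle
#'
#' Turns a community roster into every table the census pipeline consumes.
#' Coverage follows the Lander-Waterman breadth model with the strain
#' penalty; rRNA detection follows [rrna_detected()]; KO annotations realize
#' each organism's planted trophy status against the synthetic module
#' library; quality scores, taxonomy, a manifest, and a sparse ANI table
#' (within-genus pairs, all below the species threshold) complete the
#' bundle. Duplicated samples receive byte-identical coverage and rRNA rows.
#' Ground truth (presence, detection tiers, roles, planted statuses) is
#' retained for recovery testing. Regeneration under the same configuration
#' is byte-identical.
#'
#' @param config A [simulation_config()].
#' @param community Optionally a pre-built [simulate_community()] roster
#'   (must have been built from the same config for determinism).
#' @return A `simulated_bundle`: list of tibbles `coverage`, `quality`,
#'   `taxonomy`, `ko`, `rrna`, `manifest`, `ani`, `truth`, plus `organisms`,
#'   `name_map`, `duplicate_pairs`, `modules`, `rules`, and the config.
#' @export
generate_bundle <- function(config = simulation_config(),
                            community = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(community)) community <- simulate_community(config)
  stopifnot(inherits(community, "lichen_community"))
  set.seed(config$seed + 1L)

  organisms <- community$organisms
  manifest <- community$manifest
  membership <- community$membership
  rules <- synthetic_vitamin_rules()
  modules <- synthetic_module_library()

  is_dup <- !is.na(manifest$duplicate_of)
  orig_manifest <- manifest[!is_dup, ]

  # per sample x member organism: depth, reads, breadth, rRNA tiers
  rows <- membership |>
    filter(.data$sample_id %in% orig_manifest$sample_id) |>
    left_join(orig_manifest[, c("sample_id", "total_depth_bp", "read_length")],
              by = "sample_id") |>
    left_join(organisms[, c("organism_id", "genome_size", "rrna_copies",
                            "rrna_length", "strain_multiplicity")],
              by = "organism_id") |>
    arrange(.data$sample_id, .data$organism_id)

  expected_depth <- depth_for_organism(rows$total_depth_bp, rows$mass_fraction,
                                       rows$genome_size)
  n_reads <- round(expected_depth * rows$genome_size / rows$read_length)
  depth <- depth_of_coverage(n_reads, rows$read_length, rows$genome_size)
  breadth <- breadth_from_depth(depth, rows$strain_multiplicity,
                                config$strain_penalty)
  det <- rrna_detected(
    depth, rows$rrna_copies, rows$rrna_length, rows$read_length,
    min_reads = config$min_rrna_reads,
    strain_multiplicity = rows$strain_multiplicity,
    penalty = config$strain_penalty,
    breadth_threshold = config$breadth_threshold
  )

  coverage <- tibble(
    sample_id = rows$sample_id, mag_id = rows$organism_id,
    breadth = breadth, depth = depth, n_reads = n_reads,
    read_length = rows$read_length, mag_length = rows$genome_size
  )
  truth <- tibble(
    sample_id = rows$sample_id, organism_id = rows$organism_id,
    mass_fraction = rows$mass_fraction, depth = depth, breadth = breadth,
    present = breadth >= config$breadth_threshold,
    read_rrna = det$read_tier, assembly_rrna = det$assembly_tier
  )
  rrna <- dplyr::bind_rows(
    tibble(sample_id = rows$sample_id, mag_id = rows$organism_id,
           tier = "assembly", detected = det$assembly_tier),
    tibble(sample_id = rows$sample_id, mag_id = rows$organism_id,
           tier = "read", detected = det$read_tier)
  ) |>
    arrange(.data$sample_id, .data$mag_id, .data$tier)

  # duplicated deposits: byte-identical rows under the duplicate's id
  if (any(is_dup)) {
    dup <- manifest[is_dup, c("sample_id", "duplicate_of")]
    copy_rows <- function(tbl, id_col = "sample_id") {
      copied <- purrr::map2(dup$sample_id, dup$duplicate_of, function(d, s) {
        block <- tbl[tbl[[id_col]] == s, , drop = FALSE]
        block[[id_col]] <- rep(d, nrow(block))
        block
      })
      dplyr::bind_rows(tbl, copied) |> arrange(.data$sample_id, .data$mag_id)
    }
    coverage <- copy_rows(coverage)
    rrna <- copy_rows(rrna) |>
      arrange(.data$sample_id, .data$mag_id, .data$tier)
    truth_dup <- purrr::map2(dup$sample_id, dup$duplicate_of, function(d, s) {
      block <- truth[truth$sample_id == s, , drop = FALSE]
      block$sample_id <- rep(d, nrow(block))
      block
    })
    truth <- dplyr::bind_rows(truth, truth_dup) |>
      arrange(.data$sample_id, .data$organism_id)
  }

  # genome quality: most organisms near-complete; a seeded minority degraded
  n_org <- nrow(organisms)
  completeness <- pmin(100, runif(n_org, 90, 99.8))
  contamination <- runif(n_org, 0, 4)
  degraded <- runif(n_org) < 0.2
  completeness[degraded] <- runif(sum(degraded), 60, 94.9)
  tax <- parse_lineage(organisms$organism_id, organisms$lineage)
  domain_class <- dplyr::case_when(
    tax$domain == "Fungi" ~ "fungi",
    tax$domain == "Algae" ~ "algae",
    TRUE ~ "bacteria"
  )
  quality <- tibble(
    mag_id = organisms$organism_id,
    completeness = round(completeness, 2),
    contamination = round(contamination, 2),
    domain = domain_class
  )

  # planted KO annotations (route variant cycles per organism)
  org_annot <- organisms |>
    mutate(variant = row_number())
  ko <- purrr::map(seq_len(nrow(org_annot)), function(i) {
    kos <- planted_ko_set(org_annot[i, ], rules, modules)
    if (length(kos) == 0L) return(NULL)
    tibble(genome_id = org_annot$organism_id[i], ko = kos)
  })
  ko <- dplyr::bind_rows(ko)

  # within-genus ANI below the species threshold; other pairs omitted
  ani <- tax |>
    select("mag_id", "genus") |>
    inner_join(tax |> select(mag_b = "mag_id", "genus"), by = "genus",
               relationship = "many-to-many") |>
    filter(.data$mag_id < .data$mag_b) |>
    mutate(
      ani = round(runif(dplyr::n(), 80, 90), 2),
      af = round(runif(dplyr::n(), 30, 60), 2)
    ) |>
    select(mag_a = "mag_id", "mag_b", "ani", "af")

  structure(
    list(coverage = coverage, quality = quality, taxonomy = tax, ko = ko,
         rrna = rrna, manifest = manifest, ani = ani, truth = truth,
         organisms = org_annot, name_map = community$name_map,
         duplicate_pairs = community$duplicate_pairs,
         modules = modules, rules = rules, config = config),
    class = "simulated_bundle"
  )
}

#' @export
print.simulated_bundle <- function(x, ...) {
  cat(sprintf("<simulated_bundle: %d samples, %d organisms, seed %d>\n",
              nrow(x$manifest), nrow(x$organisms), x$config$seed))
  invisible(x)
}
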