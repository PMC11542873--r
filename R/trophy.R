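#' Vitamin route rules
#'
#' A rule set names, per vitamin, the KEGG modules and named KO combinations
#' that qualify an organism as a de-novo synthesizer (prototroph) or as a
#' salvager. The default rule content used by the simulator and examples is
#' [synthetic_vitamin_rules()]; real analyses supply their own module ids,
#' definitions, and KO combinations (e.g. biotin ring assembly via M00123 or
#' M00950, the thiamine salvage module M00899 or the thiMDE trio, cobalamin
#' via M00122 for prokaryotes and M00925 for eukaryotes).
#'
#' @param vitamins Named list; each element is a list with any of
#'   `synthesis_modules` (character), `salvage_modules` (character),
#'   `synthesis_gene_sets`, `salvage_gene_sets` (named lists of KO vectors,
#'   each a conjunction).
#' @param genes Named list of single marker KOs, e.g.
#'   `list(metE = "K25316", metH = "K00548")`.
#' @return An object of class `vitamin_rules`.
#' @export
vitamin_rules <- function(vitamins, genes = list()) {
  stopifnot(is.list(vitamins), length(vitamins) > 0L,
            !is.null(names(vitamins)), all(nzchar(names(vitamins))))
  for (v in names(vitamins)) {
    rule <- vitamins[[v]]
    n_routes <- length(rule$synthesis_modules) + length(rule$salvage_modules) +
      length(rule$synthesis_gene_sets) + length(rule$salvage_gene_sets)
    if (n_routes == 0L) {
      abort(sprintf("vitamin_rules(): vitamin '%s' has no qualifying route", v))
    }
  }
  structure(list(vitamins = vitamins, genes = genes), class = "vitamin_rules")
}

#' @rdname vitamin_rules
#' @param path A YAML file with top-level keys `vitamins` and optionally
#'   `genes`, in the structure accepted by `vitamin_rules()`.
#' @export
read_vitamin_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  vitamin_rules(raw$vitamins, genes = raw$genes %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate one route (module id or KO conjunction) -> fraction/complete/rescue
route_eval <- function(route, kos, parsed_modules, resolve) {
  if (is.character(route) && length(route) == 1L && grepl("^M\\d{5}$", route)) {
    m <- parsed_modules[[route]]
    if (is.null(m)) {
      abort(sprintf("missing module definition for '%s': supply it in 'modules'", route))
    }
    comp <- module_completeness(m, kos, resolve = resolve)
    one <- partial_one_missing(m, kos, resolve = resolve)
    list(fraction = comp$fraction, complete = comp$complete,
         one_missing = one$partial_one_missing)
  } else {
    # named KO conjunction (e.g. thiMDE)
    present <- route %in% kos
    list(fraction = mean(present), complete = all(present),
         one_missing = sum(!present) == 1L)
  }
}

classify_one_vitamin <- function(kos, rule, parsed_modules, resolve) {
  synth <- c(as.list(rule$synthesis_modules %||% character()),
             unname(rule$synthesis_gene_sets %||% list()))
  salv <- c(as.list(rule$salvage_modules %||% character()),
            unname(rule$salvage_gene_sets %||% list()))
  synth_ev <- purrr::map(synth, route_eval, kos = kos,
                         parsed_modules = parsed_modules, resolve = resolve)
  salv_ev <- purrr::map(salv, route_eval, kos = kos,
                        parsed_modules = parsed_modules, resolve = resolve)
  fractions <- purrr::map_dbl(c(synth_ev, salv_ev), "fraction")
  status <- if (any(purrr::map_lgl(synth_ev, "complete"))) {
    "prototroph"
  } else if (any(purrr::map_lgl(salv_ev, "complete"))) {
    "salvage_only"
  } else if (length(fractions) > 0L && max(fractions) > 0) {
    "partial"
  } else {
    "auxotroph"
  }
  list(
    status = status,
    fraction = if (length(fractions) > 0L) max(fractions) else 0,
    synthesis_one_missing = any(purrr::map_lgl(synth_ev, "one_missing"))
  )
}

#' Classify vitamin trophy status of one genome
#'
#' For each vitamin in the rules, an organism is a `prototroph` when any
#' de-novo synthesis route is complete; `salvage_only` when no synthesis
#' route is complete but a salvage route is; `partial` when the best route
#' fraction is strictly between 0 and 1 without qualifying; and `auxotroph`
#' when every route fraction is 0. The one-missing-gene variant of each
#' synthesis route is reported side by side (`*_one_missing`) but never
#' upgrades the status. Marker genes (e.g. metE/metH) are screened as simple
#' presence flags, and cobalamin dependence is derived from them.
#'
#' @param kos Character vector of KO identifiers annotated in the genome.
#' @param rules A [vitamin_rules()] object.
#' @param modules Tibble of module definitions (`module_id`, `definition`)
#'   covering every module the rules reference; missing definitions raise an
#'   error naming the module.
#' @param resolve Optional resolution mapping for nested module references.
#' @param genome_id Optional id recorded in the output.
#' @return A one-row tibble: per vitamin `<vitamin>_status`,
#'   `<vitamin>_fraction`, `<vitamin>_one_missing`; per marker gene a logical
#'   flag; plus `cobalamin_dependence` when both metE and metH are declared.
#' @export
classify_trophy <- function(kos, rules, modules, resolve = NULL,
                            genome_id = NA_character_) {
  stopifnot(inherits(rules, "vitamin_rules"))
  parsed <- parse_rule_modules(rules, modules)
  out <- tibble(genome_id = genome_id)
  for (v in names(rules$vitamins)) {
    res <- classify_one_vitamin(kos, rules$vitamins[[v]], parsed, resolve)
    out[[paste0(v, "_status")]] <- res$status
    out[[paste0(v, "_fraction")]] <- res$fraction
    out[[paste0(v, "_one_missing")]] <- res$synthesis_one_missing
  }
  for (g in names(rules$genes)) {
    out[[g]] <- all(rules$genes[[g]] %in% kos)
  }
  if (all(c("metE", "metH") %in% names(out))) {
    out$cobalamin_dependence <- classify_cobalamin_dependence(out$metE, out$metH)
  }
  out
}

# parse every module the rules reference, once
parse_rule_modules <- function(rules, modules) {
  wanted <- unique(unlist(purrr::map(rules$vitamins, function(r) {
    c(r$synthesis_modules, r$salvage_modules)
  })))
  wanted <- wanted[grepl("^M\\d{5}$", wanted %||% character())]
  if (length(wanted) == 0L) return(list())
  stopifnot(is.data.frame(modules),
            all(c("module_id", "definition") %in% names(modules)))
  missing <- setdiff(wanted, modules$module_id)
  if (length(missing) > 0L) {
    abort(sprintf("missing module definition for '%s': supply it in 'modules'",
                  missing[1L]))
  }
  defs <- modules[match(wanted, modules$module_id), ]
  setNames(
    purrr::map2(defs$definition, defs$module_id,
                ~ parse_module_definition(.x, module_id = .y)),
    wanted
  )
}

#' @rdname classify_trophy
#' @param ko_table Long tibble `genome_id`, `ko`; genomes with no rows are
#'   permitted via `genome_ids`.
#' @param genome_ids Optional full genome universe (genomes without any KO
#'   annotation are classified from the empty set).
#' @export
trophy_profiles <- function(ko_table, rules, modules, resolve = NULL,
                            genome_ids = NULL) {
  stopifnot(is.data.frame(ko_table),
            all(c("genome_id", "ko") %in% names(ko_table)))
  ids <- if (is.null(genome_ids)) {
    sort(unique(ko_table$genome_id))
  } else {
    unique(genome_ids)
  }
  sets <- split(ko_table$ko, ko_table$genome_id)
  dplyr::bind_rows(purrr::map(ids, function(g) {
    classify_trophy(sets[[g]] %||% character(), rules, modules,
                    resolve = resolve, genome_id = g)
  }))
}

#' Cobalamin dependence from methionine-synthase gene content
#'
#' metE is the cobalamin-independent methionine synthase, metH the
#' cobalamin-dependent one. An organism with only metE is independent of
#' cobalamin for methionine synthesis; with both it is a facultative user
#' (able to switch to metE when cobalamin is absent); with only metH it is
#' dependent; with neither, its requirement cannot be inferred.
#'
#' @param metE,metH Logical flags (vectorized).
#' @return Character vector in `{"independent", "facultative", "dependent",
#'   "unknown"}`.
#' @export
classify_cobalamin_dependence <- function(metE, metH) {
  dplyr::case_when(
    metE & !metH ~ "independent",
    metE & metH ~ "facultative",
    !metE & metH ~ "dependent",
    TRUE ~ "unknown"
  )
}

#' Select highly complete metagenomes for cross-feeding analysis
#'
#' A metagenome qualifies when it contains, among its present MAGs, a
#' near-complete genome for each of three roles: the LFS, a photobiont
#' (alga or cyanobacterium — in tripartite lichens either partner counts),
#' and at least one focal bacterium. Near-complete means completeness >=
#' `min_completeness` and contamination <= `max_contamination`.
#'
#' @param occ A `lichen_occurrence`.
#' @param quality Tibble `mag_id`, `completeness`, `contamination`.
#' @param roles Tibble `mag_id`, `role` with roles in
#'   `{LFS, alga, cyanobacterium, yeast, bacterium}`.
#' @param focal_bacteria Optional mag ids restricting which bacteria count
#'   (e.g. members of the high-frequency genera); default all `bacterium`
#'   roles.
#' @param min_completeness,max_contamination Near-complete bounds (percent).
#' @return A tibble `sample_id`, `qualifies`, `n_lfs`, `n_photobiont`,
#'   `n_bacteria`, `mag_ids` (list column of the qualifying near-complete
#'   present MAGs).
#' @export
select_highly_complete_metagenomes <- function(occ, quality, roles,
                                               focal_bacteria = NULL,
                                               min_completeness = 95,
                                               max_contamination = 10) {
  stopifnot(inherits(occ, "lichen_occurrence"),
            all(c("mag_id", "completeness", "contamination") %in% names(quality)),
            all(c("mag_id", "role") %in% names(roles)))
  nearc <- quality |>
    filter(is_near_complete(.data$completeness, .data$contamination,
                            min_completeness, max_contamination)) |>
    pull("mag_id")
  role_of <- setNames(roles$role, roles$mag_id)
  pres <- present_calls(occ) |>
    filter(.data$mag_id %in% nearc) |>
    mutate(role = unname(role_of[.data$mag_id])) |>
    filter(!is.na(.data$role))
  if (!is.null(focal_bacteria)) {
    pres <- pres |>
      filter(.data$role != "bacterium" | .data$mag_id %in% focal_bacteria)
  }
  per_sample <- pres |>
    group_by(.data$sample_id) |>
    summarise(
      n_lfs = sum(.data$role == "LFS"),
      n_photobiont = sum(.data$role %in% c("alga", "cyanobacterium")),
      n_bacteria = sum(.data$role == "bacterium"),
      mag_ids = list(sort(.data$mag_id)),
      .groups = "drop"
    )
  tibble(sample_id = occurrence_samples(occ)) |>
    left_join(per_sample, by = "sample_id") |>
    mutate(
      across(c("n_lfs", "n_photobiont", "n_bacteria"),
             ~ dplyr::coalesce(.x, 0L)),
      mag_ids = purrr::map(.data$mag_ids, ~ .x %||% character()),
      qualifies = .data$n_lfs >= 1L & .data$n_photobiont >= 1L & .data$n_bacteria >= 1L
    ) |>
    select("sample_id", "qualifies", "n_lfs", "n_photobiont", "n_bacteria", "mag_ids")
}

#' Assess vitamin complementarity within one metagenome
#'
#' For each vitamin for which the sample's LFS cannot synthesize de novo
#' (status `auxotroph` or `salvage_only`; optionally also `partial`), lists
#' the co-occurring prototrophs that could provide it. Organisms with
#' partial pathways are reported separately and never count as
#' complementing.
#'
#' @param members A tibble describing the present near-complete MAGs of one
#'   sample: columns `genome_id`, `role`, and the `<vitamin>_status` columns
#'   produced by [trophy_profiles()]. Exactly one row must have role `LFS`.
#' @param vitamins Vitamins to assess; defaults to every `<vitamin>_status`
#'   column present.
#' @param sample_id Recorded in the output.
#' @param include_partial_lfs Also assess vitamins for which the LFS status
#'   is `partial`.
#' @return A tibble `sample_id`, `vitamin`, `lfs_status`, `providers` (list
#'   column of `genome_id (role)` strings), `n_providers`,
#'   `partial_providers` (list column), `complemented`.
#' @export
assess_complementarity <- function(members, vitamins = NULL,
                                   sample_id = NA_character_,
                                   include_partial_lfs = FALSE) {
  stopifnot(is.data.frame(members), all(c("genome_id", "role") %in% names(members)))
  lfs <- members |> filter(.data$role == "LFS")
  if (nrow(lfs) == 0L) abort("assess_complementarity(): no LFS profile among members")
  if (nrow(lfs) > 1L) abort("assess_complementarity(): more than one LFS profile among members")
  if (is.null(vitamins)) {
    vitamins <- sub("_status$", "",
                    grep("_status$", names(members), value = TRUE))
  }
  needy <- c("auxotroph", "salvage_only", if (include_partial_lfs) "partial")
  rows <- purrr::map(vitamins, function(v) {
    col <- paste0(v, "_status")
    if (!col %in% names(members)) {
      abort(sprintf("assess_complementarity(): no '%s' column in members", col))
    }
    lfs_status <- lfs[[col]]
    if (!lfs_status %in% needy) return(NULL)
    others <- members |> filter(.data$role != "LFS")
    prov <- others |> filter(.data[[col]] == "prototroph")
    part <- others |> filter(.data[[col]] == "partial")
    tibble(
      sample_id = sample_id,
      vitamin = v,
      lfs_status = lfs_status,
      providers = list(sprintf("%s (%s)", prov$genome_id, prov$role)),
      n_providers = nrow(prov),
      partial_providers = list(sprintf("%s (%s)", part$genome_id, part$role)),
      complemented = nrow(prov) >= 1L
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(sample_id = character(), vitamin = character(),
                  lfs_status = character(), providers = list(),
                  n_providers = integer(), partial_providers = list(),
                  complemented = logical())
  }
  out
}

#' Prevalence of a trophy status
#'
#' Integer-percent share of genomes with a given status for a vitamin,
#' optionally within a genome subset (e.g. the annotated bacterial MAGs).
#'
#' @param profiles Output of [trophy_profiles()].
#' @param vitamin Vitamin name.
#' @param status Status counted (default `prototroph`).
#' @param subset Optional genome ids forming the denominator.
#' @return One-row tibble: `vitamin`, `status`, `n`, `denominator`, `pct`.
#' @export
trophy_prevalence <- function(profiles, vitamin, status = "prototroph",
                              subset = NULL) {
  col <- paste0(vitamin, "_status")
  stopifnot(col %in% names(profiles))
  rows <- if (is.null(subset)) profiles else profiles |>
    filter(.data$genome_id %in% subset)
  if (nrow(rows) == 0L) abort("trophy_prevalence(): empty genome subset")
  n <- sum(rows[[col]] == status)
  tibble(vitamin = vitamin, status = status, n = n,
         denominator = nrow(rows), pct = pct_round(n, nrow(rows)))
}
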