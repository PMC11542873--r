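rules <- synthetic_vitamin_rules()
modules <- synthetic_module_library()

test_that("trophy classification follows the route rules", {
  # a complete biotin ring-assembly route makes a prototroph
  proto <- classify_trophy(ko_for_status("biotin", "prototroph"), rules, modules)
  expect_identical(proto$biotin_status, "prototroph")
  # the thiMDE trio alone is thiamine salvage, not synthesis
  thimde <- classify_trophy(c("K90211", "K90212", "K90213"), rules, modules)
  expect_identical(thimde$thiamine_status, "salvage_only")
  expect_identical(thimde$biotin_status, "auxotroph")
  # an empty KO set is auxotrophic for every vitamin
  none <- classify_trophy(character(), rules, modules)
  expect_identical(none$biotin_status, "auxotroph")
  expect_identical(none$thiamine_status, "auxotroph")
  expect_identical(none$cobalamin_status, "auxotroph")
  # a strict subset of a synthesis route is partial
  part <- classify_trophy("K90101", rules, modules)
  expect_identical(part$biotin_status, "partial")
  expect_gt(part$biotin_fraction, 0)
  expect_lt(part$biotin_fraction, 1)
})

test_that("every genome gets exactly one status per vitamin", {
  fx <- simulate_annotated_mags(n = 20, n_biotin_prototrophs = 8)
  prof <- trophy_profiles(fx$ko, rules, modules,
                          genome_ids = fx$planted$genome_id)
  for (col in c("biotin_status", "thiamine_status", "cobalamin_status")) {
    expect_true(all(prof[[col]] %in%
                      c("prototroph", "salvage_only", "partial", "auxotroph")))
  }
  expect_equal(nrow(prof), 20L)
})

test_that("planted statuses are recovered exactly", {
  fx <- simulate_annotated_mags()
  prof <- trophy_profiles(fx$ko, fx$rules, fx$modules,
                          genome_ids = fx$planted$genome_id)
  merged <- dplyr::inner_join(prof, fx$planted, by = "genome_id",
                              suffix = c("", "_planted"))
  expect_identical(merged$biotin_status, merged$biotin_status_planted)
  expect_identical(merged$thiamine_status, merged$thiamine_status_planted)
  expect_identical(merged$cobalamin_status, merged$cobalamin_status_planted)
})

test_that("biotin prototrophy prevalence matches the planted share", {
  fx <- simulate_annotated_mags(n = 63, n_biotin_prototrophs = 27)
  prof <- trophy_profiles(fx$ko, fx$rules, fx$modules,
                          genome_ids = fx$planted$genome_id)
  p <- trophy_prevalence(prof, "biotin")
  expect_equal(p$n, 27L)
  expect_equal(p$denominator, 63L)
  expect_equal(p$pct, 43L)
  expect_equal(trophy_prevalence(prof, "thiamine", status = "prototroph")$n, 0L)
})

test_that("adding KOs never demotes a trophy status", {
  rank_of <- c(auxotroph = 0, partial = 1, salvage_only = 1, prototroph = 2)
  pool <- unique(c(unlist(lapply(modules$definition, function(d) {
    regmatches(d, gregexpr("K\\d{5}", d))[[1]]
  })), "K90211", "K90212", "K90213"))
  withr::with_seed(404, {
    for (rep in 1:100) {
      a <- sample(pool, sample(0:6, 1))
      b <- union(a, sample(pool, sample(0:6, 1)))
      pa <- classify_trophy(a, rules, modules)
      pb <- classify_trophy(b, rules, modules)
      for (v in c("biotin", "thiamine", "cobalamin")) {
        col <- paste0(v, "_status")
        expect_gte(rank_of[[pb[[col]]]], rank_of[[pa[[col]]]])
        expect_gte(pb[[paste0(v, "_fraction")]], pa[[paste0(v, "_fraction")]])
      }
    }
  })
})

test_that("cobalamin dependence follows metE/metH content", {
  expect_identical(classify_cobalamin_dependence(TRUE, FALSE), "independent")
  expect_identical(classify_cobalamin_dependence(TRUE, TRUE), "facultative")
  expect_identical(classify_cobalamin_dependence(FALSE, TRUE), "dependent")
  expect_identical(classify_cobalamin_dependence(FALSE, FALSE), "unknown")
  # marker genes feed through classify_trophy
  alga <- classify_trophy(c("K90401", "K90402"), rules, modules)
  expect_true(alga$metE && alga$metH)
  expect_identical(alga$cobalamin_dependence, "facultative")
})

test_that("a missing module definition is reported by name", {
  bad_rules <- vitamin_rules(list(biotin = list(synthesis_modules = "M00999")))
  expect_error(classify_trophy("K90101", bad_rules, modules), "M00999")
})

# a 40-sample collection with exactly 7 planted qualifying metagenomes
planted_quality_fixture <- function() {
  samples <- sprintf("q%02d", 1:40)
  qualifying <- samples[c(2, 7, 12, 19, 23, 31, 38)]
  quality <- tibble::tibble(
    mag_id = c("lfs_hi", "lfs_lo", "alga_hi", "bact_hi", "bact_lo"),
    completeness = c(98, 94.9, 97, 99, 98),
    contamination = c(1, 0, 2, 0.5, 12)
  )
  roles <- tibble::tibble(
    mag_id = quality$mag_id,
    role = c("LFS", "LFS", "alga", "bacterium", "bacterium")
  )
  cov <- dplyr::bind_rows(
    # qualifying: near-complete LFS + alga + bacterium all present
    tidyr::expand_grid(sample_id = qualifying,
                       mag_id = c("lfs_hi", "alga_hi", "bact_hi")),
    # near misses: a role absent or only its degraded genome present
    tidyr::expand_grid(sample_id = setdiff(samples, qualifying)[1:11],
                       mag_id = c("lfs_lo", "alga_hi", "bact_hi")),
    tidyr::expand_grid(sample_id = setdiff(samples, qualifying)[12:22],
                       mag_id = c("lfs_hi", "alga_hi", "bact_lo")),
    tidyr::expand_grid(sample_id = setdiff(samples, qualifying)[23:33],
                       mag_id = c("lfs_hi", "bact_hi"))
  ) |>
    dplyr::mutate(breadth = 0.9)
  occ <- call_occurrence(cov, samples = samples,
                         species = quality$mag_id)
  list(occ = occ, quality = quality, roles = roles, qualifying = qualifying)
}

test_that("highly complete metagenome selection returns exactly the planted set", {
  fx <- planted_quality_fixture()
  sel <- select_highly_complete_metagenomes(fx$occ, fx$quality, fx$roles)
  expect_setequal(sel$sample_id[sel$qualifies], fx$qualifying)
  # the boundary genome (completeness 94.9) never counts as near-complete
  expect_false(any(purrr::map_lgl(sel$mag_ids, ~ "lfs_lo" %in% .x)))
})

test_that("complementarity lists providers only where the LFS needs them", {
  members <- tibble::tibble(
    genome_id = c("lfs1", "alga1", "bact1", "bact2"),
    role = c("LFS", "alga", "bacterium", "bacterium"),
    biotin_status = c("auxotroph", "prototroph", "prototroph", "partial"),
    thiamine_status = c("prototroph", "salvage_only", "auxotroph", "auxotroph"),
    cobalamin_status = c("auxotroph", "partial", "auxotroph", "auxotroph")
  )
  rep <- assess_complementarity(members, sample_id = "m1")
  biotin <- rep[rep$vitamin == "biotin", ]
  expect_true(biotin$complemented)
  expect_equal(biotin$n_providers, 2L)
  expect_setequal(biotin$providers[[1]],
                  c("alga1 (alga)", "bact1 (bacterium)"))
  expect_identical(biotin$partial_providers[[1]], "bact2 (bacterium)")
  # thiamine skipped: the LFS synthesizes it
  expect_false("thiamine" %in% rep$vitamin)
  # cobalamin: needed but nobody provides; partial pathways never complement
  cob <- rep[rep$vitamin == "cobalamin", ]
  expect_false(cob$complemented)
  expect_equal(cob$n_providers, 0L)
  # complemented always names a provider
  expect_true(all(!rep$complemented | rep$n_providers >= 1))
  expect_error(assess_complementarity(members[members$role != "LFS", ]),
               "no LFS")
})
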