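# definitions exercising every construct: blocks, alternatives, complexes,
# optional subunits, nesting, and the missing-step placeholder
tricky_definitions <- c(
  "K00001 K00002",
  "(K00001,K00002) K00003",
  "K00001+K00002-K00003",
  "K00001+K00002 K00003",
  "(K00001,K00002) (K00003,K00004)",
  "(K00001,K00002 K00003) K00004",
  "K00001 (K00002,K00003+K00004)",
  "K00001-K00002+K00003",
  "-K00001 K00002",
  "(K00001,K00002+K00003-K00004)",
  "K00001 -- K00002"
)

all_subsets <- function(kos) {
  unlist(lapply(0:length(kos), function(k) {
    combn(kos, k, simplify = FALSE)
  }), recursive = FALSE)
}

test_that("parsing counts blocks and classifies structures as the grammar dictates", {
  expect_length(module_blocks(parse_module_definition("K00001 K00002")), 2L)
  m <- parse_module_definition("(K00001,K00002) K00003")
  blocks <- module_blocks(m)
  expect_length(blocks, 2L)
  expect_identical(blocks[[1]]$kind, "alt")
  m2 <- parse_module_definition("K00001+K00002-K00003")
  expect_length(module_blocks(m2), 1L)
  # the optional subunit carries no requirement
  expect_true(block_present(module_blocks(m2)[[1]], c("K00001", "K00002")))
  expect_false(block_present(module_blocks(m2)[[1]], c("K00001", "K00003")))
  # a '-'-prefixed top-level unit is excluded from the block count
  expect_length(module_blocks(parse_module_definition("-K00001 K00002")), 1L)
})

test_that("malformed definitions fail with a position", {
  expect_error(parse_module_definition("(K00001 K00002"), "unbalanced")
  expect_error(parse_module_definition("K00001+"), "position")
  expect_error(parse_module_definition("K00001 K2"), "neither a KO")
  expect_error(parse_module_definition(""), "non-empty")
  expect_error(parse_module_definition("K00001,)K00002"), "position")
})

test_that("parse -> serialize -> parse is a fixed point", {
  for (def in tricky_definitions) {
    m1 <- parse_module_definition(def)
    s1 <- format_module(m1)
    m2 <- parse_module_definition(s1)
    expect_identical(format_module(m2), s1, label = def)
    # and semantics survive the round trip
    kos_all <- oracle_all_kos(def)
    for (kos in all_subsets(kos_all)[c(1, 3, 7)]) {
      expect_identical(module_completeness(m2, kos)$fraction,
                       module_completeness(m1, kos)$fraction, label = def)
    }
  }
})

test_that("completeness agrees with the truth-table oracle on every subset", {
  for (def in tricky_definitions) {
    m <- parse_module_definition(def)
    kos_all <- oracle_all_kos(def)
    for (kos in all_subsets(kos_all)) {
      got <- module_completeness(m, kos)
      expect_equal(got$fraction, oracle_completeness(def, kos),
                   label = sprintf("%s with {%s}", def, paste(kos, collapse = ",")))
      expect_identical(got$complete, got$fraction == 1)
    }
  }
})

test_that("worked completeness fractions match hand evaluation", {
  expect_equal(module_completeness(parse_module_definition("K00001 K00002"),
                                   "K00001")$fraction, 0.5)
  expect_equal(module_completeness(
    parse_module_definition("(K00001,K00002) (K00003,K00004)"),
    c("K00002", "K00003"))$fraction, 1)
  # empty KO set on a module without optional-only blocks scores zero
  expect_equal(module_completeness(parse_module_definition("K00001 K00002"),
                                   character())$fraction, 0)
  # the missing-step placeholder is never satisfied
  gap <- parse_module_definition("K00001 -- K00002")
  expect_equal(module_completeness(gap, c("K00001", "K00002"))$fraction, 2 / 3)
})

test_that("a module with no required block has undefined completeness", {
  expect_error(module_completeness(parse_module_definition("-K00001"),
                                   "K00001"), "no non-optional blocks")
})

test_that("one missing gene can rescue a module, two cannot", {
  m <- parse_module_definition("K00001 K00002 K00003")
  res <- partial_one_missing(m, c("K00001", "K00002"))
  expect_true(res$partial_one_missing)
  expect_identical(res$rescuing_ko, "K00003")
  m2 <- parse_module_definition("K00001+K00002 K00003")
  expect_false(partial_one_missing(m2, "K00003")$partial_one_missing)
  expect_false(partial_one_missing(m, c("K00001", "K00002", "K00003"))$partial_one_missing)
  # exhaustive check against single-KO augmentation of the oracle
  for (def in tricky_definitions) {
    m <- parse_module_definition(def)
    kos_all <- oracle_all_kos(def)
    for (kos in all_subsets(kos_all)) {
      want <- oracle_completeness(def, kos) < 1 &&
        any(vapply(setdiff(kos_all, kos), function(k) {
          oracle_completeness(def, c(kos, k)) == 1
        }, logical(1)))
      expect_identical(partial_one_missing(m, kos)$partial_one_missing, want,
                       label = sprintf("%s with {%s}", def, paste(kos, collapse = ",")))
    }
  }
})

test_that("completeness is monotone under KO-set growth", {
  withr::with_seed(2024, {
    for (rep in 1:300) {
      def <- random_definition()
      m <- parse_module_definition(def)
      pool <- oracle_all_kos(def)
      a <- sample(pool, sample(0:length(pool), 1))
      b <- union(a, sample(pool, sample(0:length(pool), 1)))
      expect_lte(module_completeness(m, a)$fraction,
                 module_completeness(m, b)$fraction)
    }
  })
})

test_that("nested module references resolve through the mapping or fail loudly", {
  m <- parse_module_definition("(M00001,K00001) K00002")
  expect_error(module_completeness(m, c("K00001", "K00002")), "unresolved")
  res <- list(M00001 = c("K00010", "K00011"))
  expect_equal(module_completeness(m, c("K00010", "K00011"), resolve = res)$fraction, 0.5)
  expect_true(module_completeness(m, c("K00001", "K00002"), resolve = res)$complete)
  # a definition string also works as a resolution target
  res2 <- list(M00001 = "K00010 (K00011,K00012)")
  expect_true(module_completeness(m, c("K00010", "K00012", "K00002"),
                                  resolve = res2)$complete)
})

test_that("completeness_table evaluates every genome against every module", {
  modules <- synthetic_module_library()
  ko <- tibble::tibble(
    genome_id = c("g1", "g1", "g2"),
    ko = c("K90101", "K90102", "K90301")
  )
  tbl <- completeness_table(modules, ko)
  expect_equal(nrow(tbl), 2L * nrow(modules))
  g2_cob <- tbl[tbl$genome_id == "g2" & tbl$module_id == "M00122", ]
  expect_equal(g2_cob$fraction, 0.25)
  expect_false(g2_cob$complete)
})
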