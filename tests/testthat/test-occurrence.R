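test_that("depth of coverage is reads x length / genome", {
  expect_equal(depth_of_coverage(1000, 150, 1.5e6), 0.1)
  expect_equal(depth_of_coverage(0, 150, 1.5e6), 0)
  expect_equal(depth_of_coverage(2e6, 100, 5e7), 4.0)
  expect_error(depth_of_coverage(10, 150, 0), "mag_length")
})

test_that("presence is inclusive at the breadth threshold", {
  cov <- tibble::tibble(
    sample_id = c("s1", "s1", "s2"),
    mag_id = c("a", "b", "a"),
    breadth = c(0.50, 0.499, 0.8)
  )
  occ <- call_occurrence(cov)
  m <- occurrence_matrix(occ)
  expect_equal(m["s1", "a"], 1L)
  expect_equal(m["s1", "b"], 0L)
  expect_equal(m["s2", "a"], 1L)
  expect_error(call_occurrence(tibble::tibble(sample_id = "s", mag_id = "a",
                                              breadth = 1.2)),
               "breadth")
})

test_that("the incidence matrix equals an elementwise threshold oracle", {
  withr::with_seed(12, {
    cov <- tidyr::expand_grid(sample_id = c("s1", "s2", "s3"),
                              mag_id = c("a", "b", "c", "d")) |>
      dplyr::mutate(breadth = round(runif(12), 3))
    occ <- call_occurrence(cov)
    m <- occurrence_matrix(occ)
    oracle <- matrix(as.integer(cov$breadth >= 0.5), nrow = 3, byrow = TRUE,
                     dimnames = list(c("s1", "s2", "s3"), c("a", "b", "c", "d")))
    expect_identical(m, oracle)
    # raising the threshold never adds occurrences
    for (th in c(0.3, 0.5, 0.7, 0.9)) {
      m_th <- occurrence_matrix(call_occurrence(cov, breadth_min = th))
      expect_true(all(m_th <= occurrence_matrix(call_occurrence(cov, breadth_min = th - 0.2))))
    }
  })
})

test_that("relative abundance is the depth ratio against the LFS", {
  expect_equal(relative_abundance(30, 30), 1)
  expect_equal(relative_abundance(0.5, 50), 0.01) # the ~1:100 yeast regime
  expect_equal(relative_abundance(0, 10), 0)
  expect_true(is.na(relative_abundance(1, 0)))
})

test_that("LFS assignment prefers the deepest fungal MAG, ties by id", {
  tax <- tibble::tibble(
    mag_id = c("f1", "f2", "b1"),
    domain = c("Fungi", "Fungi", "Bacteria"),
    genus = c("Cladonia", "Peltigera", "Lichenihabitans")
  )
  cov <- tibble::tibble(
    sample_id = c("s1", "s2", "s2", "s3", "s3", "s4"),
    mag_id = c("f1", "f1", "f2", "f1", "f2", "b1"),
    breadth = 0.9
  )
  depths <- tibble::tibble(
    sample_id = c("s1", "s2", "s2", "s3", "s3", "s4"),
    mag_id = c("f1", "f1", "f2", "f1", "f2", "b1"),
    depth = c(10, 30, 3, 5, 5, 40)
  )
  occ <- call_occurrence(cov)
  calls <- assign_lfs(occ, depths, tax)
  expect_identical(calls$lfs_mag_id[calls$sample_id == "s1"], "f1")
  expect_identical(calls$lfs_mag_id[calls$sample_id == "s2"], "f1") # deeper
  expect_identical(calls$lfs_mag_id[calls$sample_id == "s3"], "f1") # tie -> id
  expect_identical(calls$status[calls$sample_id == "s4"], "none_found")
})

test_that("verification distinguishes verified, reassigned, corrected, misassigned", {
  tax <- tibble::tibble(
    mag_id = c("f1", "f2"),
    domain = "Fungi",
    genus = c("Cladonia", "Peltigera")
  )
  name_map <- tibble::tibble(
    name = c("Cladonia stellaris", "Peltigera canina"),
    genus = c("Cladonia", "Peltigera")
  )
  cov <- tibble::tibble(
    sample_id = c("v", "r", "r", "c", "m", "u"),
    mag_id = c("f1", "f1", "f2", "f1", "f1", "f1"),
    breadth = 0.9
  )
  depths <- tibble::tibble(
    sample_id = cov$sample_id, mag_id = cov$mag_id,
    depth = c(30, 30, 3, 30, 30, 30)
  )
  manifest <- tibble::tibble(
    sample_id = c("v", "r", "c", "m", "u"),
    declared_lfs_name = c("Cladonia stellaris", "Peltigera canina",
                          "Peltigera canina", "Peltigera canina",
                          "Xanthoria parietina"),
    library_name = c(NA, NA, "Cladonia stellaris", NA, NA)
  )
  occ <- call_occurrence(cov)
  calls <- assign_lfs(occ, depths, tax)
  final <- verify_lfs(calls, manifest, name_map, tax, occ = occ, depths = depths)
  status <- setNames(final$status, final$sample_id)
  expect_identical(unname(status[c("v", "r", "c", "m", "u")]),
                   c("verified", "reassigned", "name_corrected",
                     "misassigned", "misassigned"))
  # the reassigned call moved to the matching fungal MAG
  expect_identical(final$lfs_mag_id[final$sample_id == "r"], "f2")
  expect_identical(final$corrected_name[final$sample_id == "c"],
                   "Cladonia stellaris")
  # the unresolvable name records a reason
  expect_match(final$reason[final$sample_id == "u"], "could not be resolved")
})

test_that("the filtering cascade reproduces the printed stage counts", {
  cas <- run_cascade_fixture(simulate_cascade_fixture())
  s <- glance(cas)
  expect_equal(s$n_total, 437L)
  expect_equal(s$n_no_mag, 62L)
  expect_equal(s$n_dataset1, 375L)
  expect_equal(s$n_with_fungal_mag, 348L)
  expect_equal(s$n_misassigned, 18L)
  expect_equal(s$n_dataset2, 330L)
  labels <- tidy(cas)
  # Dataset 2 is nested in Dataset 1, which is nested in the manifest
  expect_true(all(!labels$in_dataset2 | labels$in_dataset1))
  expect_true(s$n_dataset2 <= s$n_dataset1)
  expect_true(s$n_dataset1 <= s$n_total)
})

test_that("a collection with no recoverable MAGs yields empty datasets", {
  manifest <- tibble::tibble(sample_id = c("x1", "x2"),
                             declared_lfs_name = "Cladonia stellaris")
  cov <- tibble::tibble(sample_id = c("x1", "x2"), mag_id = "f1",
                        breadth = 0.1)
  tax <- tibble::tibble(mag_id = "f1", domain = "Fungi", genus = "Cladonia")
  occ <- call_occurrence(cov)
  calls <- assign_lfs(occ, NULL, tax)
  calls <- verify_lfs(calls, manifest,
                      tibble::tibble(name = "Cladonia stellaris",
                                     genus = "Cladonia"), tax)
  s <- glance(build_dataset_cascade(manifest, occ, calls))
  expect_equal(s$n_dataset1, 0L)
  expect_equal(s$n_dataset2, 0L)
})
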