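test_that("primer coverage counts planted records and rounds half-up", {
  pools <- shipped_pools()
  fx <- make_reference_db(fixture_spec(41, n_records = 10, f_both = 0.7),
                          pools[["27f_simple"]], pools[["534r"]])
  rep_f <- primer_coverage(fx$db, pools[["27f_simple"]])
  expect_equal(rep_f$matched_count, 7L)
  expect_equal(rep_f$percent, 70.0)
  rep_r <- primer_coverage(fx$db, pools[["534r"]])
  expect_equal(rep_r$matched_count, 7L)

  none <- primer_coverage(fx$db, pools[["967f"]])
  expect_equal(none$matched_count, 0L)
  expect_equal(none$percent, 0)

  empty <- structure(list(ids = character(0)), class = "reference_db")
  expect_error(primer_coverage(empty, pools[["515f"]]), "empty")
})

test_that("pair coverage separates pessimistic from optimistic accounting", {
  pools <- shipped_pools()
  fx <- make_reference_db(fixture_spec(42, n_records = 10, f_both = 0.3,
                                       f_rev_only = 0.4,
                                       truncated_fraction = 0.4),
                          pools[["27f_simple"]], pools[["534r"]])
  pess <- pair_coverage(fx$db, pools[["27f_simple"]], pools[["534r"]],
                        "pessimistic")
  opti <- pair_coverage(fx$db, pools[["27f_simple"]], pools[["534r"]],
                        "optimistic")
  expect_equal(pess$percent, 30.0)
  expect_equal(opti$percent, 70.0)
  expect_equal(opti$matched_count - pess$matched_count, 4L)
})

test_that("pair coverage never exceeds either single-primer coverage", {
  pools <- shipped_pools()
  for (seed in 51:53) {
    fx <- make_reference_db(fixture_spec(seed, n_records = 20, f_both = 0.5,
                                         f_fwd_only = 0.2, f_rev_only = 0.2),
                            pools[["27f_simple"]], pools[["534r"]])
    pess <- pair_coverage(fx$db, pools[["27f_simple"]], pools[["534r"]],
                          "pessimistic")
    opti <- pair_coverage(fx$db, pools[["27f_simple"]], pools[["534r"]],
                          "optimistic")
    f_cov <- primer_coverage(fx$db, pools[["27f_simple"]])
    r_cov <- primer_coverage(fx$db, pools[["534r"]])
    expect_lte(pess$matched_count, min(f_cov$matched_count, r_cov$matched_count))
    expect_gte(opti$matched_count, pess$matched_count)
  }
})

test_that("genus coverage matrix recovers per-genus plantings and conserves counts", {
  pools <- shipped_pools()
  plan <- list(list(genus = "Lactobacillus", species = "crispatus", count = 4L,
                    f_both = 1),
               list(genus = "Gardnerella", species = "vaginalis", count = 3L,
                    f_both = 0),
               list(genus = "Prevotella", species = "bivia", count = 3L,
                    f_both = 2/3))
  fx <- make_reference_db(fixture_spec(43, genus_plan = plan, f_both = 0),
                          pools[["27f_simple"]], pools[["534r"]])
  pairs <- list(list(fwd = pools[["27f_simple"]], rev = pools[["534r"]],
                     approach = "pessimistic"))
  mat <- genus_coverage_matrix(fx$db, pairs)
  expect_equal(sort(rownames(mat)),
               sort(c("Lactobacillus", "Gardnerella", "Prevotella")))
  expect_equal(mat["Lactobacillus", 1], 100)
  expect_equal(mat["Gardnerella", 1], 0)
  expect_equal(mat["Prevotella", 1], 100 * 2 / 3)

  # record-weighted column mean reconstructs the pair's matched count exactly
  counts <- attr(mat, "genus_counts")
  pair_cov <- pair_coverage(fx$db, pools[["27f_simple"]], pools[["534r"]],
                            "pessimistic")
  expect_equal(sum(counts[rownames(mat)] * mat[, 1] / 100),
               pair_cov$matched_count)

  expect_error(genus_coverage_matrix(fx$db, list()), "empty")
})

test_that("records without a genus aggregate under (unassigned)", {
  pools <- shipped_pools()
  fx <- make_reference_db(fixture_spec(44, n_records = 4, f_both = 1),
                          pools[["27f_simple"]], pools[["534r"]])
  db <- fx$db
  db$lineages[[2]] <- parse_lineage("Bacteria;Firmicutes")
  mat <- genus_coverage_matrix(db, list(list(fwd = pools[["27f_simple"]],
                                             rev = pools[["534r"]])))
  expect_true("(unassigned)" %in% rownames(mat))
  expect_equal(unname(attr(mat, "genus_counts")["(unassigned)"]), 1L)
})

test_that("amplification bias follows the closed form with its monotonicities", {
  expect_equal(amplification_bias(1.9, 30), (2 / 1.9)^30)
  expect_equal(amplification_bias(2.0, 17), 1.0)
  expect_equal(amplification_bias(1.5, 0), 1.0)
  # strictly increasing in cycles, strictly decreasing in efficiency
  expect_true(all(diff(vapply(0:20, function(cc) amplification_bias(1.9, cc),
                              numeric(1))) > 0))
  effs <- seq(1.1, 2.0, by = 0.1)
  expect_true(all(diff(vapply(effs, function(e) amplification_bias(e, 10),
                              numeric(1))) < 0))
  expect_error(amplification_bias(0.9, 10), "efficiency")
  expect_error(amplification_bias(2.1, 10), "efficiency")
  expect_error(amplification_bias(1.9, -1), "cycles")
})

test_that("coverage TSV outputs keep Table-style columns", {
  pools <- shipped_pools()
  fx <- make_reference_db(fixture_spec(45, n_records = 6, f_both = 0.5),
                          pools[["27f_simple"]], pools[["534r"]])
  dir <- withr::local_tempdir()
  rep <- rbind(primer_coverage(fx$db, pools[["27f_simple"]]),
               primer_coverage(fx$db, pools[["534r"]]))
  f <- write_coverage_tsv(rep, file.path(dir, "cov.tsv"))
  back <- read.delim(f)
  expect_equal(names(back),
               c("subject", "approach", "matched_count", "database_size",
                 "percent"))
  mat <- genus_coverage_matrix(fx$db, list(list(fwd = pools[["27f_simple"]],
                                                rev = pools[["534r"]])))
  g <- write_coverage_tsv(mat, file.path(dir, "mat.tsv"))
  gm <- read.delim(g, check.names = FALSE)
  expect_equal(names(gm)[1:2], c("genus", "n_records"))
  expect_equal(gm[[3]], 50.0)
})
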