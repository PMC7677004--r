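make_pair_fixture <- function(seed, ...) {
  pools <- shipped_pools()
  fx <- make_reference_db(fixture_spec(seed, ...),
                          pools[["27f_simple"]], pools[["534r"]])
  c(fx, list(fwd = pools[["27f_simple"]], rev = pools[["534r"]]))
}

test_that("extract_amplicon pairs the planted sites with correct coordinates", {
  fx <- make_pair_fixture(21, n_records = 8, f_both = 1)
  for (i in seq_len(8)) {
    ex <- extract_amplicon(fx$db$sequences[[i]], fx$fwd, fx$rev,
                           record_id = fx$db$ids[i])
    expect_equal(ex$status, "amplified")
    expect_equal(ex$outer_span,
                 c(fx$truth$fwd_start[i], fx$truth$rev_end[i]))
    expect_equal(ex$inner_span,
                 c(fx$truth$fwd_end[i], fx$truth$rev_start[i]))
    expect_equal(diff(ex$inner_span), fx$truth$inner_len[i])
    expect_true(ex$inner_span[1] >= ex$outer_span[1] &&
                ex$inner_span[2] <= ex$outer_span[2])
  }
})

test_that("missing sites produce the matching failure statuses", {
  fx <- make_pair_fixture(22, n_records = 9, f_both = 0,
                          f_fwd_only = 1/3, f_rev_only = 1/3)
  for (i in seq_len(9)) {
    ex <- extract_amplicon(fx$db$sequences[[i]], fx$fwd, fx$rev,
                           five_prime_complete = "complete")
    want <- switch(fx$truth$category[i],
                   fwd_only = "no_reverse",
                   rev_only = "no_forward",
                   none = "no_forward")
    expect_equal(ex$status, want)
  }
})

test_that("optimistic mode credits 5'-truncated reverse-only records", {
  fx <- make_pair_fixture(23, n_records = 10, f_both = 0.3, f_rev_only = 0.5,
                          truncated_fraction = 0.4)
  statuses <- vapply(seq_len(10), function(i) {
    extract_amplicon(fx$db$sequences[[i]], fx$fwd, fx$rev, mode = "optimistic",
                     five_prime_complete = fx$db$five_prime_complete[i])$status
  }, character(1))
  expect_equal(sum(statuses == "amplified"), 3L)
  expect_equal(sum(statuses == "assumed_amplified"), 4L)
  # assumed only on flagged-truncated records
  expect_equal(statuses == "assumed_amplified",
               fx$truth$five_prime_complete == "truncated")
})

test_that("mode is irrelevant when both sites are present", {
  fx <- make_pair_fixture(24, n_records = 5, f_both = 1)
  for (i in 1:5) {
    res <- lapply(c("plain", "pessimistic", "optimistic"), function(m) {
      extract_amplicon(fx$db$sequences[[i]], fx$fwd, fx$rev, mode = m,
                       five_prime_complete = "truncated")
    })
    expect_equal(res[[1]]$status, "amplified")
    expect_equal(res[[1]]$inner_span, res[[2]]$inner_span)
    expect_equal(res[[2]]$inner_span, res[[3]]$inner_span)
  }
})

test_that("truncation classification: metadata wins, heuristic otherwise", {
  pools <- shipped_pools()
  fwd <- pools[["27f_simple"]]; rev <- pools[["534r"]]
  site <- data.frame(start = 80L, end = 97L)
  expect_equal(classify_truncation("ACGT", "truncated", fwd, rev, site),
               "truncated")
  expect_equal(classify_truncation("ACGT", "complete", fwd, rev, site),
               "complete")
  # expected upstream = 534 - 27 = 507; 80 < 507 - 100 -> truncated
  expect_equal(classify_truncation("ACGT", "unknown", fwd, rev, site),
               "truncated")
  far_site <- data.frame(start = 520L, end = 537L)
  expect_equal(classify_truncation("ACGT", "unknown", fwd, rev, far_site),
               "complete")
  # boundary: exactly expected - slack is not truncated
  edge_site <- data.frame(start = 407L, end = 424L)
  expect_equal(classify_truncation("ACGT", "unknown", fwd, rev, edge_site),
               "complete")
  nopos <- primer_pool("x", degenerate_primer("x", "ACGTACGTAC"))
  expect_error(classify_truncation("ACGT", "unknown", nopos, rev, site),
               "expected_position")
})

test_that("read simulation follows the merge / paired / both length rules", {
  pools <- shipped_pools()
  fwd <- pools[["27f_simple"]]; rev <- pools[["534r"]]
  sim_one <- function(inner_len, seed) {
    fx <- make_reference_db(
      fixture_spec(seed, n_records = 1, f_both = 1,
                   inner_len_range = c(inner_len, inner_len),
                   len_range = c(inner_len + 200L, inner_len + 250L)),
      fwd, rev)
    ex <- extract_amplicon(fx$db$sequences[[1]], fwd, rev)
    list(sim = simulate_reads(fx$db$sequences[[1]], ex,
                              truth = fx$db$lineages[[1]]),
         inner = substring(fx$db$sequences[[1]], ex$inner_span[1] + 1,
                           ex$inner_span[2]))
  }

  s400 <- sim_one(400L, 31)
  expect_equal(s400$sim$representation, "merged")
  expect_equal(nchar(s400$sim$merged_seq), 400L)
  expect_equal(s400$sim$merged_seq, s400$inner)

  s600 <- sim_one(600L, 32)
  expect_equal(s600$sim$representation, "paired")
  expect_equal(nchar(s600$sim$fwd_read), 250L)
  expect_equal(s600$sim$fwd_read, substring(s600$inner, 1, 250))
  expect_equal(s600$sim$rev_read,
               reverse_complement(substring(s600$inner, 351, 600)))

  s495 <- sim_one(495L, 33)
  expect_equal(s495$sim$representation, "both")
  expect_equal(nchar(s495$sim$merged_seq), 495L)
  # paired reads reconstruct the insert when L <= 2 * read_len
  recon <- paste0(substring(s495$sim$fwd_read, 1, 495 - 250),
                  reverse_complement(s495$sim$rev_read))
  expect_equal(recon, s495$inner)

  ex_bad <- list(status = "no_forward")
  expect_error(simulate_reads("ACGT", ex_bad), "amplified")
})

test_that("simulated output files carry reads and lineages", {
  pools <- shipped_pools()
  fwd <- pools[["27f_simple"]]; rev <- pools[["534r"]]
  fx <- make_reference_db(fixture_spec(34, n_records = 3, f_both = 1,
                                       inner_len_range = c(600L, 620L),
                                       len_range = c(900L, 950L)),
                          fwd, rev)
  sims <- lapply(1:3, function(i) {
    ex <- extract_amplicon(fx$db$sequences[[i]], fwd, rev,
                           record_id = fx$db$ids[i])
    simulate_reads(fx$db$sequences[[i]], ex, truth = fx$db$lineages[[i]])
  })
  dir <- withr::local_tempdir()
  files <- write_simulated(sims, file.path(dir, "sim"), format = "fastq")
  expect_true(all(file.exists(files)))
  r1 <- Biostrings::readDNAStringSet(file.path(dir, "sim_R1.fastq"),
                                     format = "fastq")
  expect_length(r1, 3L)
  expect_match(names(r1)[1], "Lactobacillus")
})
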