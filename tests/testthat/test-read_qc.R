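test_that("quality truncation removes maximal-sum low-quality tails", {
  r_hi <- quality_read("hi", strrep("A", 50), rep(30L, 50))
  expect_identical(quality_truncate(r_hi, 15L), r_hi)

  # trailing Q2 run removed entirely
  r_tail <- quality_read("t", strrep("A", 60), c(rep(35L, 50), rep(2L, 10)))
  out <- quality_truncate(r_tail, 15L)
  expect_equal(length(out$quals), 50L)
  expect_equal(out$sequence, strrep("A", 50))

  # uniformly bad read collapses to empty
  r_bad <- quality_read("b", strrep("A", 20), rep(2L, 20))
  expect_equal(nchar(quality_truncate(r_bad, 15L)$sequence), 0L)

  # output is always a prefix and never longer than the input
  set.seed(61)
  for (i in 1:50) {
    n <- sample(5:120, 1L)
    q <- sample(0:40, n, replace = TRUE)
    rd <- quality_read("x", paste(sample(c("A","C","G","T"), n, TRUE),
                                  collapse = ""), q)
    tr <- quality_truncate(rd, 15L)
    expect_lte(length(tr$quals), n)
    expect_equal(tr$sequence, substring(rd$sequence, 1, length(tr$quals)))
    # brute-force oracle over all cut positions
    expect_equal(length(tr$quals), oracle_truncate_keep(q, 15L))
  }
})

test_that("expected errors follow the Phred closed form", {
  expect_equal(expected_errors(rep(20L, 10)), 0.1)
  expect_equal(expected_errors(integer(0)), 0)
  # 540 bases at Q15 exceed the default ceiling of 4
  ee15 <- expected_errors(rep(15L, 540))
  expect_equal(ee15, 540 * 10^-1.5)
  expect_gt(ee15, 4)
  # 540 bases at Q30 stay well under it
  expect_equal(expected_errors(rep(30L, 540)), 0.54)
  expect_error(expected_errors(c(10L, -1L)), "negative")

  # monotone under any per-base quality increase; additive over concatenation
  set.seed(62)
  for (i in 1:20) {
    q <- sample(2:40, 30, replace = TRUE)
    up <- q; j <- sample(30, 5); up[j] <- up[j] + sample(1:10, 5, TRUE)
    expect_lte(expected_errors(up), expected_errors(q))
    q2 <- sample(2:40, 11, replace = TRUE)
    expect_equal(expected_errors(c(q, q2)),
                 expected_errors(q) + expected_errors(q2))
  }
})

test_that("concat_filter applies the short and expected-error rules", {
  params <- qc_params()
  mk <- function(id, n, q) quality_read(id, strrep("A", n), rep(q, n))

  kept <- concat_filter(mk("a", 280, 30L), mk("a", 280, 30L), params)
  expect_equal(kept$status, "kept")
  expect_equal(kept$ee_value, 0.54)
  expect_equal(nchar(kept$concatenated$sequence), 540L)
  expect_equal(length(kept$concatenated$quals), 540L)

  # forward read trimmed below 270 bp -> rejected short
  short_f <- quality_read("s", strrep("A", 280), c(rep(30L, 250), rep(2L, 30)))
  expect_equal(concat_filter(short_f, mk("s", 280, 30L), params)$status,
               "rejected_short")

  # reads of exactly 270 bp pass the length check
  exact <- concat_filter(mk("e", 270, 38L), mk("e", 270, 38L), params)
  expect_equal(exact$status, "kept")

  # EE over the concatenated 540 bp above 4 -> rejected
  ee_fail <- concat_filter(mk("q", 270, 16L), mk("q", 270, 16L), params)
  expect_equal(ee_fail$status, "rejected_ee")
  expect_equal(ee_fail$ee_value, 540 * 10^-1.6)
})

test_that("batch filtering matches the brute-force oracle on engineered batches", {
  for (seed in c(71, 72)) {
    fq <- make_fastq_pairs(fastq_spec(seed, n_pairs = 20, f_fail_short = 0.3,
                                      f_fail_ee = 0.25))
    res <- concat_filter_batch(fq$pairs)
    expect_equal(res$status, fq$truth$expected_status)
    oracle <- mapply(function(f, r) oracle_concat_status(f$quals, r$quals),
                     fq$pairs$fwd, fq$pairs$rev)
    expect_equal(res$status, unname(oracle))
    expect_equal(sum(res$status == "rejected_short"), 6L)
    expect_equal(sum(res$status == "rejected_ee"), 5L)
    kept <- attr(res, "kept")
    expect_true(all(vapply(kept, function(k) nchar(k$sequence), integer(1)) == 540L))
  }

  # randomly assorted (non-engineered) qualities: oracle agreement still exact
  set.seed(73)
  fwd <- lapply(1:30, function(i) {
    n <- sample(250:300, 1L)
    quality_read(paste0("r", i), paste(sample(c("A","C","G","T"), n, TRUE),
                                       collapse = ""),
                 sample(2:40, n, replace = TRUE))
  })
  rev <- lapply(1:30, function(i) {
    n <- sample(250:300, 1L)
    quality_read(paste0("r", i), paste(sample(c("A","C","G","T"), n, TRUE),
                                       collapse = ""),
                 sample(2:40, n, replace = TRUE))
  })
  res2 <- concat_filter_batch(list(fwd = fwd, rev = rev))
  oracle2 <- mapply(function(f, r) oracle_concat_status(f$quals, r$quals),
                    fwd, rev)
  expect_equal(res2$status, unname(oracle2))
})

test_that("FASTQ pairs round-trip through Phred+33 files", {
  fq <- make_fastq_pairs(fastq_spec(74, n_pairs = 5, f_fail_short = 0.2))
  dir <- withr::local_tempdir()
  write_fastq(fq$pairs$fwd, file.path(dir, "R1.fastq"))
  write_fastq(fq$pairs$rev, file.path(dir, "R2.fastq"))
  back <- read_fastq_pairs(file.path(dir, "R1.fastq"), file.path(dir, "R2.fastq"))
  expect_equal(length(back$fwd), 5L)
  for (i in 1:5) {
    expect_equal(back$fwd[[i]]$id, fq$pairs$fwd[[i]]$id)
    expect_equal(back$fwd[[i]]$sequence, fq$pairs$fwd[[i]]$sequence)
    expect_equal(back$fwd[[i]]$quals, fq$pairs$fwd[[i]]$quals)
  }
  # filtering the re-read pairs matches filtering the in-memory ones
  expect_equal(concat_filter_batch(back)$status,
               concat_filter_batch(fq$pairs)$status)
})
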