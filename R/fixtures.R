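# Run fn with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards; fixtures are reproducible without clobbering user code.
with_fixture_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# sample one integer from [lo, hi]; safe for degenerate ranges (sample(x, 1)
# on a scalar would draw from 1:x)
sample_range <- function(lo, hi) {
  if (lo >= hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
}

#' Specification for a planted-site reference database fixture
#'
#' Describes a synthetic reference database with exactly controlled primer
#' site composition, so that coverage statistics computed from it have an
#' exact, known truth. Fractions are converted to record counts by
#' half-up rounding and must be mutually consistent.
#'
#' @param seed Integer seed; identical seeds give byte-identical databases.
#' @param n_records Number of records (ignored when `genus_plan` is given).
#' @param f_both,f_fwd_only,f_rev_only Fractions of records planted with
#'   both primer sites, the forward site only, or the reverse site only;
#'   the remainder get no site.
#' @param truncated_fraction Fraction of records flagged 5'-truncated;
#'   these are drawn from the reverse-only records (a record missing its 5'
#'   end has lost the forward locus but not the reverse one).
#' @param genus_plan Optional list of per-genus entries, each a list with
#'   `genus`, `species`, `count` and optionally the four fractions above
#'   (defaulting to the global ones); counts define `n_records`.
#' @param len_range Background sequence length range (bases).
#' @param inner_len_range Range of the planted insert length between the
#'   two primer sites.
#' @param fwd_offset_range Range of the forward-site start offset.
#' @return A list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(seed, n_records = 10L, f_both = 0.7, f_fwd_only = 0,
                         f_rev_only = 0, truncated_fraction = 0,
                         genus_plan = NULL, len_range = c(900L, 1000L),
                         inner_len_range = c(250L, 420L),
                         fwd_offset_range = c(20L, 60L)) {
  fracs <- c(f_both, f_fwd_only, f_rev_only, truncated_fraction)
  stopifnot(all(fracs >= 0), all(fracs <= 1), f_both + f_fwd_only + f_rev_only <= 1)
  if (is.null(genus_plan)) {
    genus_plan <- list(list(genus = "Lactobacillus", species = "crispatus",
                            count = as.integer(n_records)))
  }
  genus_plan <- lapply(genus_plan, function(e) {
    if (is.null(e$f_both)) e$f_both <- f_both
    if (is.null(e$f_fwd_only)) e$f_fwd_only <- f_fwd_only
    if (is.null(e$f_rev_only)) e$f_rev_only <- f_rev_only
    if (is.null(e$truncated_fraction)) e$truncated_fraction <- truncated_fraction
    if (is.null(e$species)) e$species <- "sp"
    e
  })
  structure(list(seed = as.integer(seed), genus_plan = genus_plan,
                 len_range = as.integer(len_range),
                 inner_len_range = as.integer(inner_len_range),
                 fwd_offset_range = as.integer(fwd_offset_range)),
            class = "fixture_spec")
}

count_split <- function(n, f_both, f_fwd, f_rev, f_trunc) {
  n_both <- as.integer(round_half_up(n * f_both, 0))
  n_fwd <- as.integer(round_half_up(n * f_fwd, 0))
  n_rev <- as.integer(round_half_up(n * f_rev, 0))
  if (n_both + n_fwd + n_rev > n) {
    stop("planted fractions are mutually inconsistent (counts exceed n)", call. = FALSE)
  }
  n_trunc <- as.integer(round_half_up(n * f_trunc, 0))
  if (n_trunc > n_rev) {
    stop("truncated_fraction exceeds the reverse-only fraction; truncated ",
         "records must be reverse-only by construction", call. = FALSE)
  }
  list(both = n_both, fwd_only = n_fwd, rev_only = n_rev,
       none = n - n_both - n_fwd - n_rev, trunc = n_trunc)
}

# one background sequence free of any site for the given pools
clean_background <- function(n, fwd, rev, max_tries = 50L) {
  for (i in seq_len(max_tries)) {
    s <- random_bases(n)
    if (nrow(find_sites(s, fwd)) == 0L && nrow(find_sites(s, rev)) == 0L) return(s)
  }
  stop("could not generate primer-free background after ", max_tries,
       " attempts", call. = FALSE)
}

random_variant <- function(pool) {
  m <- pool$members[[sample.int(length(pool$members), 1L)]]
  v <- expand_degenerate(m)
  v[sample.int(length(v), 1L)]
}

#' Generate a reference database with planted primer sites
#'
#' Builds a synthetic database in which every record's amplification outcome
#' for the given primer pair is known exactly: backgrounds are rejection
#' sampled until free of spurious sites, then concrete primer variants are
#' planted at recorded coordinates, and the assembled record is verified to
#' contain exactly the planted sites. Identical seed, identical output.
#'
#' @param spec A [fixture_spec()].
#' @param fwd,rev Forward and reverse [primer_pool()]s the sites are planted
#'   for.
#' @return A list with `db` (a `reference_db`) and `truth`, a data.frame
#'   with one row per record: `id`, `genus`, `species`, `category`
#'   (both/fwd_only/rev_only/none), `five_prime_complete`, planted
#'   `fwd_start`, `fwd_end`, `rev_start`, `rev_end` (0-based half-open; NA
#'   when unplanted) and `inner_len`.
#' @export
make_reference_db <- function(spec, fwd, rev) {
  fwd <- as_pool(fwd); rev <- as_pool(rev)
  with_fixture_seed(spec$seed, function() {
    rows <- list(); ids <- character(0); seqs <- character(0)
    lineages <- list(); five <- character(0)
    idx <- 0L
    for (entry in spec$genus_plan) {
      n <- entry$count
      cs <- count_split(n, entry$f_both, entry$f_fwd_only, entry$f_rev_only,
                        entry$truncated_fraction)
      cats <- c(rep("both", cs$both), rep("fwd_only", cs$fwd_only),
                rep("rev_only", cs$rev_only), rep("none", cs$none))
      trunc_flags <- c(rep(FALSE, cs$both + cs$fwd_only),
                       rep(TRUE, cs$trunc), rep(FALSE, cs$rev_only - cs$trunc),
                       rep(FALSE, cs$none))
      for (k in seq_len(n)) {
        idx <- idx + 1L
        id <- sprintf("rec%04d", idx)
        built <- build_planted_record(spec, fwd, rev, cats[k])
        ids <- c(ids, id); seqs <- c(seqs, built$seq)
        lineages[[idx]] <- new_lineage(c("Bacteria", "Firmicutes", "Bacilli",
                                         "Lactobacillales", "Lactobacillaceae",
                                         entry$genus, entry$species))
        five <- c(five, if (trunc_flags[k]) "truncated" else "complete")
        rows[[idx]] <- data.frame(
          id = id, genus = entry$genus, species = entry$species,
          category = cats[k],
          five_prime_complete = five[idx],
          fwd_start = built$fwd_start, fwd_end = built$fwd_end,
          rev_start = built$rev_start, rev_end = built$rev_end,
          inner_len = built$inner_len, stringsAsFactors = FALSE)
      }
    }
    names(seqs) <- ids
    db <- new_reference_db(ids, seqs, lineages, five,
                           source_label = paste0("synthetic-seed", spec$seed))
    list(db = db, truth = do.call(rbind, rows))
  })
}

# assemble one record with the requested planting category, verifying that
# exactly the planted sites are present
build_planted_record <- function(spec, fwd, rev, category, max_tries = 50L) {
  for (try in seq_len(max_tries)) {
    total_len <- sample_range(spec$len_range[1], spec$len_range[2])
    off <- sample_range(spec$fwd_offset_range[1], spec$fwd_offset_range[2])
    inner <- sample_range(spec$inner_len_range[1], spec$inner_len_range[2])
    fvar <- random_variant(fwd)
    rvar <- reverse_complement(random_variant(rev))  # template-sense
    fs <- fe <- rs <- re <- NA_integer_; inner_len <- NA_integer_
    if (category == "both") {
      need <- off + nchar(fvar) + inner + nchar(rvar)
      suffix_len <- max(total_len - need, 30L)
      s <- paste0(random_bases(off), fvar, random_bases(inner), rvar,
                  random_bases(suffix_len))
      fs <- off; fe <- off + nchar(fvar)
      rs <- fe + inner; re <- rs + nchar(rvar)
      inner_len <- inner
    } else if (category == "fwd_only") {
      s <- paste0(random_bases(off), fvar,
                  random_bases(max(total_len - off - nchar(fvar), 30L)))
      fs <- off; fe <- off + nchar(fvar)
    } else if (category == "rev_only") {
      rs0 <- max(total_len - nchar(rvar) - 40L, 10L)
      s <- paste0(random_bases(rs0), rvar, random_bases(40L))
      rs <- rs0; re <- rs0 + nchar(rvar)
    } else {
      s <- random_bases(total_len)
    }
    fhits <- find_sites(s, fwd); rhits <- find_sites(s, rev)
    want_f <- if (!is.na(fs)) data.frame(start = fs, end = fe) else data.frame()
    want_r <- if (!is.na(rs)) data.frame(start = rs, end = re) else data.frame()
    ok_f <- nrow(fhits) == nrow(want_f) &&
      (nrow(want_f) == 0L || (fhits$start == want_f$start && fhits$end == want_f$end))
    ok_r <- nrow(rhits) == nrow(want_r) &&
      (nrow(want_r) == 0L || (rhits$start == want_r$start && rhits$end == want_r$end))
    if (ok_f && ok_r) {
      return(list(seq = s, fwd_start = fs, fwd_end = fe,
                  rev_start = rs, rev_end = re, inner_len = inner_len))
    }
  }
  stop("failed to assemble a planted record after ", max_tries, " attempts",
       call. = FALSE)
}

#' Specification for a synthetic FASTQ pair batch
#'
#' Pairs are engineered so their fate under the default [qc_params()] is
#' known by construction: passing pairs are uniformly high quality (Q38,
#' expected error over 540 bp well under 4); short-failing pairs end in a
#' long Q2 tail that the 3' quality trim removes, leaving the forward read
#' under 270 bp; EE-failing pairs are uniform Q16 — above the Phred-15 trim
#' cutoff, so untrimmed, but with 540 x 10^-1.6 ~ 13.6 expected errors.
#'
#' @param seed Integer seed.
#' @param n_pairs Number of read pairs.
#' @param read_len Raw read length (default 280).
#' @param f_fail_short,f_fail_ee Fractions engineered to fail the length
#'   and expected-error filters (counts by half-up rounding; the remainder
#'   pass).
#' @return A list of class `"fastq_spec"`.
#' @export
fastq_spec <- function(seed, n_pairs = 10L, read_len = 280L,
                       f_fail_short = 0, f_fail_ee = 0) {
  stopifnot(f_fail_short >= 0, f_fail_ee >= 0, f_fail_short + f_fail_ee <= 1,
            read_len > 0L)
  structure(list(seed = as.integer(seed), n_pairs = as.integer(n_pairs),
                 read_len = as.integer(read_len),
                 f_fail_short = f_fail_short, f_fail_ee = f_fail_ee),
            class = "fastq_spec")
}

#' Generate a paired FASTQ batch with known QC outcomes
#'
#' @param spec A [fastq_spec()].
#' @return A list with `pairs` (list with `fwd`/`rev` [quality_read()]
#'   lists, directly consumable by [concat_filter_batch()]) and `truth`, a
#'   data.frame with `id` and `expected_status`
#'   (kept/rejected_short/rejected_ee).
#' @export
make_fastq_pairs <- function(spec) {
  with_fixture_seed(spec$seed, function() {
    n_short <- as.integer(round_half_up(spec$n_pairs * spec$f_fail_short, 0))
    n_ee <- as.integer(round_half_up(spec$n_pairs * spec$f_fail_ee, 0))
    if (n_short + n_ee > spec$n_pairs) {
      stop("failure fractions are mutually inconsistent", call. = FALSE)
    }
    classes <- c(rep("rejected_short", n_short), rep("rejected_ee", n_ee),
                 rep("kept", spec$n_pairs - n_short - n_ee))
    L <- spec$read_len
    fwd <- vector("list", spec$n_pairs); rev <- vector("list", spec$n_pairs)
    for (i in seq_len(spec$n_pairs)) {
      id <- sprintf("pair%04d", i)
      make_q <- function(cls, which_read) {
        if (cls == "rejected_short" && which_read == "fwd") {
          # Q2 tail long enough that the trimmed read falls below 270 bp
          tail_len <- L - 250L
          c(rep(38L, L - tail_len), rep(2L, tail_len))
        } else if (cls == "rejected_ee") {
          rep(16L, L)
        } else {
          rep(38L, L)
        }
      }
      fwd[[i]] <- quality_read(id, random_bases(L), make_q(classes[i], "fwd"))
      rev[[i]] <- quality_read(id, random_bases(L), make_q(classes[i], "rev"))
    }
    truth <- data.frame(id = sprintf("pair%04d", seq_len(spec$n_pairs)),
                        expected_status = classes, stringsAsFactors = FALSE)
    list(pairs = list(fwd = fwd, rev = rev), truth = truth)
  })
}
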