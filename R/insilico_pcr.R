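#' Simulation parameters for in-silico reads
#'
#' @param read_len Read length in bases (default 250, a realistic usable
#'   length after primer and quality trimming on 2x300 chemistry).
#' @param merge_threshold Amplicon length below which paired reads are
#'   merged (default 500 = 2 x 250).
#' @param near_window Half-width of the "very close to the threshold" band
#'   in which both merged and paired representations are emitted (default 10).
#' @return A list of class `"simulation_params"`.
#' @export
simulation_params <- function(read_len = 250L, merge_threshold = 500L,
                              near_window = 10L) {
  read_len <- as.integer(read_len)
  merge_threshold <- as.integer(merge_threshold)
  near_window <- as.integer(near_window)
  stopifnot(read_len > 0L, merge_threshold >= read_len, near_window >= 0L)
  structure(list(read_len = read_len, merge_threshold = merge_threshold,
                 near_window = near_window), class = "simulation_params")
}

#' Classify 5'-completeness of a reference record
#'
#' Decides whether a record lacks its 5' end (and therefore the forward
#' primer locus). The explicit `five_prime_complete` metadata flag wins when
#' present; otherwise a length heuristic is applied: the expected number of
#' bases upstream of the reverse-primer site is the difference between the
#' reverse and forward primers' expected E. coli coordinates, and a record
#' with fewer upstream bases than that (minus `slack`) is called truncated.
#'
#' @param sequence Template sequence.
#' @param five_prime_complete Metadata flag: `"complete"`, `"truncated"` or
#'   `"unknown"`.
#' @param fwd,rev Forward and reverse [primer_pool()]s (their
#'   `expected_position`s drive the heuristic).
#' @param reverse_site One row of a [find_sites()] result for the reverse
#'   pool on this record.
#' @param slack Tolerated shortfall in bases, acknowledging 16S length
#'   heterogeneity (default 100).
#' @return `"complete"` or `"truncated"`.
#' @export
classify_truncation <- function(sequence, five_prime_complete, fwd, rev,
                                reverse_site, slack = 100L) {
  if (five_prime_complete %in% c("complete", "truncated")) {
    return(five_prime_complete)
  }
  fpos <- pool_expected_position(as_pool(fwd))
  rpos <- pool_expected_position(as_pool(rev))
  if (is.na(fpos) || is.na(rpos)) {
    stop("truncation heuristic needs expected_position on both pools", call. = FALSE)
  }
  expected_upstream <- rpos - fpos
  actual_upstream <- reverse_site$start
  if (actual_upstream < expected_upstream - slack) "truncated" else "complete"
}

#' In-silico PCR: amplification outcome for one record and one primer pair
#'
#' Finds exact full-length binding sites for both pools and pairs the
#' 5'-most forward site with the 3'-most reverse site that yield a
#' positive-length insert. `plain` and `pessimistic` modes require both
#' sites; `optimistic` mode additionally reports `assumed_amplified` for
#' records with a reverse site but no forward site whose 5' end is missing
#' (classified truncated), modelling the assumption that such records would
#' have carried the forward locus had they been complete.
#'
#' @param sequence Template sequence (forward-oriented).
#' @param fwd Forward [primer_pool()].
#' @param rev Reverse [primer_pool()].
#' @param mode `"pessimistic"`, `"optimistic"` or `"plain"`.
#' @param record_id Identifier copied into the result.
#' @param five_prime_complete Metadata flag for the record
#'   (complete/truncated/unknown); used only in optimistic mode.
#' @param slack Slack passed to [classify_truncation()].
#' @return A list of class `"amplicon_extraction"` with `record_id`,
#'   `status` (amplified / assumed_amplified / no_forward / no_reverse /
#'   no_product), `forward_site`, `reverse_site`, `outer_span`, `inner_span`
#'   (0-based half-open `c(start, end)`, with and without primers), `mode`.
#' @export
extract_amplicon <- function(sequence, fwd, rev,
                             mode = c("pessimistic", "optimistic", "plain"),
                             record_id = "", five_prime_complete = "unknown",
                             slack = 100L) {
  mode <- match.arg(mode)
  fwd <- as_pool(fwd); rev <- as_pool(rev)
  if (fwd$orientation != "forward") stop("fwd pool must be forward-oriented", call. = FALSE)
  if (rev$orientation != "reverse") stop("rev pool must be reverse-oriented", call. = FALSE)
  fsites <- find_sites(sequence, fwd, record_id)
  rsites <- find_sites(sequence, rev, record_id)

  res <- list(record_id = record_id, status = NULL,
              forward_site = NULL, reverse_site = NULL,
              outer_span = NULL, inner_span = NULL, mode = mode)
  class(res) <- "amplicon_extraction"

  if (nrow(fsites) == 0L) {
    if (nrow(rsites) > 0L && mode == "optimistic") {
      rv <- rsites[nrow(rsites), , drop = FALSE]
      cls <- classify_truncation(sequence, five_prime_complete, fwd, rev, rv, slack)
      if (cls == "truncated") {
        res$status <- "assumed_amplified"
        res$reverse_site <- rv
        return(res)
      }
    }
    res$status <- "no_forward"
    return(res)
  }
  if (nrow(rsites) == 0L) {
    res$status <- "no_reverse"
    return(res)
  }
  # outermost compatible pair: 5'-most forward, 3'-most reverse with a
  # positive-length insert between them
  best <- NULL
  for (i in seq_len(nrow(fsites))) {
    f <- fsites[i, , drop = FALSE]
    ok <- rsites$start > f$end
    if (any(ok)) {
      r <- rsites[max(which(ok)), , drop = FALSE]
      best <- list(f = f, r = r)
      break
    }
  }
  if (is.null(best)) {
    res$status <- "no_product"
    return(res)
  }
  res$status <- "amplified"
  res$forward_site <- best$f
  res$reverse_site <- best$r
  res$outer_span <- c(best$f$start, best$r$end)
  res$inner_span <- c(best$f$end, best$r$start)
  res
}

#' @export
print.amplicon_extraction <- function(x, ...) {
  cat("<amplicon_extraction> ", x$record_id, ": ", x$status,
      " (", x$mode, " mode)\n", sep = "")
  if (identical(x$status, "amplified")) {
    cat("  outer [", x$outer_span[1], ", ", x$outer_span[2], "), inner [",
        x$inner_span[1], ", ", x$inner_span[2], ") len ",
        x$inner_span[2] - x$inner_span[1], "\n", sep = "")
  }
  invisible(x)
}

#' Simulate error-free sequencer reads from an amplicon
#'
#' Emulates paired-end sequencing of the primer-trimmed insert with no PCR
#' or sequencing errors. Inserts shorter than `merge_threshold - near_window`
#' are represented as a single merged sequence (the full insert); inserts
#' longer than `merge_threshold + near_window` as an independent read pair
#' (forward read = first `read_len` bases, reverse read = reverse complement
#' of the last `read_len` bases); inserts within `near_window` of the
#' threshold get both representations, since mergeability there depends on
#' sequencer accuracy.
#'
#' @param sequence Template the extraction refers to.
#' @param extraction An `"amplicon_extraction"` with status `"amplified"`.
#' @param params A [simulation_params()].
#' @param truth True lineage of the template (carried along for scoring).
#' @return A list of class `"simulated_amplicon"`: `record_id`,
#'   `representation` (merged/paired/both), `merged_seq`, `fwd_read`,
#'   `rev_read`, `true_lineage`.
#' @export
simulate_reads <- function(sequence, extraction, params = simulation_params(),
                           truth = parse_lineage("")) {
  if (!identical(extraction$status, "amplified")) {
    stop("simulate_reads requires an amplified extraction (got status '",
         extraction$status, "')", call. = FALSE)
  }
  inner <- substring(toupper(sequence), extraction$inner_span[1] + 1L,
                     extraction$inner_span[2])
  L <- nchar(inner)
  lo <- params$merge_threshold - params$near_window
  hi <- params$merge_threshold + params$near_window
  representation <- if (L < lo) "merged" else if (L > hi) "paired" else "both"
  out <- list(record_id = extraction$record_id, representation = representation,
              merged_seq = NULL, fwd_read = NULL, rev_read = NULL,
              true_lineage = truth)
  if (representation %in% c("merged", "both")) {
    out$merged_seq <- inner
  }
  if (representation %in% c("paired", "both")) {
    n <- min(params$read_len, L)
    out$fwd_read <- substring(inner, 1L, n)
    out$rev_read <- reverse_complement(substring(inner, L - n + 1L, L))
  }
  class(out) <- "simulated_amplicon"
  out
}

#' Write simulated amplicons to FASTA/FASTQ
#'
#' Merged representations are written to `<prefix>_merged.fasta`; paired
#' representations to `<prefix>_R1` / `<prefix>_R2` (`.fasta`, or `.fastq`
#' at uniform Q40 when `format = "fastq"`). The true lineage is carried in
#' each header after `truth_delim`.
#'
#' @param sims List of `"simulated_amplicon"` objects.
#' @param prefix Output path prefix.
#' @param format `"fasta"` or `"fastq"` for the paired files.
#' @param truth_delim Delimiter between read id and lineage in headers.
#' @return Invisibly, a character vector of the files written.
#' @export
write_simulated <- function(sims, prefix, format = c("fasta", "fastq"),
                            truth_delim = " ") {
  format <- match.arg(format)
  written <- character(0)
  hdr <- function(s) paste0(s$record_id, truth_delim, format_lineage(s$true_lineage))
  merged <- Filter(function(s) !is.null(s$merged_seq), sims)
  if (length(merged)) {
    x <- Biostrings::DNAStringSet(vapply(merged, `[[`, character(1), "merged_seq"))
    names(x) <- vapply(merged, hdr, character(1))
    f <- paste0(prefix, "_merged.fasta")
    Biostrings::writeXStringSet(x, f)
    written <- c(written, f)
  }
  paired <- Filter(function(s) !is.null(s$fwd_read), sims)
  if (length(paired)) {
    r1 <- Biostrings::DNAStringSet(vapply(paired, `[[`, character(1), "fwd_read"))
    r2 <- Biostrings::DNAStringSet(vapply(paired, `[[`, character(1), "rev_read"))
    names(r1) <- names(r2) <- vapply(paired, hdr, character(1))
    ext <- if (format == "fastq") ".fastq" else ".fasta"
    f1 <- paste0(prefix, "_R1", ext); f2 <- paste0(prefix, "_R2", ext)
    if (format == "fastq") {
      q1 <- Biostrings::PhredQuality(vapply(Biostrings::width(r1),
              function(w) paste(rep("I", w), collapse = ""), character(1)))
      q2 <- Biostrings::PhredQuality(vapply(Biostrings::width(r2),
              function(w) paste(rep("I", w), collapse = ""), character(1)))
      Biostrings::writeXStringSet(r1, f1, format = "fastq", qualities = q1)
      Biostrings::writeXStringSet(r2, f2, format = "fastq", qualities = q2)
    } else {
      Biostrings::writeXStringSet(r1, f1)
      Biostrings::writeXStringSet(r2, f2)
    }
    written <- c(written, f1, f2)
  }
  invisible(written)
}
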