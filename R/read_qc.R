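#' Construct a quality read
#' @param id Read identifier.
#' @param sequence Nucleotide string.
#' @param quals Integer Phred scores, one per base, in [0, 93].
#' @return A list of class `"quality_read"`.
#' @export
quality_read <- function(id, sequence, quals) {
  quals <- as.integer(quals)
  if (nchar(sequence) != length(quals)) {
    stop("sequence and quality lengths differ for read '", id, "'", call. = FALSE)
  }
  if (length(quals) && (min(quals) < 0L || max(quals) > 93L)) {
    stop("Phred scores must lie in [0, 93] (read '", id, "')", call. = FALSE)
  }
  structure(list(id = id, sequence = sequence, quals = quals),
            class = "quality_read")
}

#' QC parameters for the concatenation path
#'
#' Defaults mirror the processing of long V1-V3 amplicons that cannot be
#' merged: 3' quality trimming at Phred 15, fixed trimming to 270 bp per
#' read, and discarding pairs whose expected error over the concatenated
#' 540 bp exceeds 4.
#'
#' @param q_cutoff Phred cutoff for 3' quality trimming (default 15).
#' @param trim_len Fixed per-read length after trimming (default 270).
#' @param max_ee Maximum expected errors over the concatenated product
#'   (default 4).
#' @return A list of class `"qc_params"`; `concat_len` is always
#'   `2 * trim_len`.
#' @export
qc_params <- function(q_cutoff = 15L, trim_len = 270L, max_ee = 4.0) {
  stopifnot(q_cutoff >= 0L, trim_len > 0L, max_ee > 0)
  structure(list(q_cutoff = as.integer(q_cutoff), trim_len = as.integer(trim_len),
                 max_ee = max_ee, concat_len = 2L * as.integer(trim_len)),
            class = "qc_params")
}

#' 3'-end quality truncation by the partial-sums method
#'
#' Scanning from the 3' end, accumulates `q_cutoff - Q` per base and cuts at
#' the position where the running sum is maximal and positive; a read with
#' no positive partial sum is returned unchanged. This removes trailing
#' low-quality stretches (bases below the cutoff) while tolerating isolated
#' poor bases inside high-quality sequence. Ties in the maximal sum trim
#' the longer suffix.
#'
#' @param read A [quality_read()].
#' @param q_cutoff Phred cutoff (default 15).
#' @return A [quality_read()] that is a prefix of the input (possibly
#'   empty).
#' @export
quality_truncate <- function(read, q_cutoff = 15L) {
  q <- read$quals
  n <- length(q)
  if (n == 0L) return(read)
  s <- cumsum(q_cutoff - rev(q))  # s[i]: sum over the last i bases
  m <- max(s)
  if (m <= 0) return(read)
  cut <- max(which(s == m))  # number of 3' bases removed; ties trim more
  keep <- n - cut
  quality_read(read$id, substring(read$sequence, 1L, keep), q[seq_len(keep)])
}

#' Expected number of errors implied by Phred scores
#'
#' Sum over bases of the per-base error probability `10^(-Q/10)`.
#'
#' @param quals Integer Phred scores (or a [quality_read()]).
#' @return Nonnegative float; 0 for empty input.
#' @examples
#' expected_errors(rep(20L, 10))  # 0.1
#' @export
expected_errors <- function(quals) {
  if (inherits(quals, "quality_read")) quals <- quals$quals
  if (length(quals) == 0L) return(0)
  if (any(quals < 0)) stop("negative Phred score", call. = FALSE)
  sum(10^(-quals / 10))
}

#' Quality-filter and concatenate a read pair
#'
#' The concatenation path for amplicons too long to merge: both reads are
#' 3'-quality-truncated at `q_cutoff`; if either falls short of `trim_len`
#' the pair is rejected (`rejected_short`); otherwise both are trimmed to
#' exactly `trim_len`, and the pair is rejected (`rejected_ee`) when the
#' expected error over the concatenated `2 * trim_len` bases exceeds
#' `max_ee`. Kept pairs are returned as the concatenation of the two
#' trimmed reads, the reverse read in as-sequenced orientation (the two
#' halves are treated downstream as independent evidence, so no reverse
#' complementing).
#'
#' @param fwd,rev [quality_read()]s, already primer-trimmed.
#' @param params A [qc_params()].
#' @return A list of class `"filter_outcome"`: `status` (kept /
#'   rejected_short / rejected_ee), `concatenated` ([quality_read()] of
#'   length `concat_len` when kept), `ee_value` (expected errors of the
#'   concatenated product, present unless rejected short).
#' @export
concat_filter <- function(fwd, rev, params = qc_params()) {
  f <- quality_truncate(fwd, params$q_cutoff)
  r <- quality_truncate(rev, params$q_cutoff)
  out <- list(status = NULL, concatenated = NULL, ee_value = NULL)
  class(out) <- "filter_outcome"
  if (length(f$quals) < params$trim_len || length(r$quals) < params$trim_len) {
    out$status <- "rejected_short"
    return(out)
  }
  fq <- f$quals[seq_len(params$trim_len)]
  rq <- r$quals[seq_len(params$trim_len)]
  ee <- expected_errors(c(fq, rq))
  out$ee_value <- ee
  if (ee > params$max_ee) {
    out$status <- "rejected_ee"
    return(out)
  }
  out$status <- "kept"
  out$concatenated <- quality_read(
    paste0(fwd$id, "_concat"),
    paste0(substring(f$sequence, 1L, params$trim_len),
           substring(r$sequence, 1L, params$trim_len)),
    c(fq, rq))
  out
}

#' Read paired FASTQ files into quality reads
#' @param r1_path,r2_path FASTQ paths (Sanger/Phred+33).
#' @return A list with elements `fwd` and `rev`, each a list of
#'   [quality_read()]s in file order.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  load_one <- function(path) {
    # muffle Biostrings' internal note about dropped metadata columns; ids,
    # bases and qualities are all preserved
    x <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w), fixed = TRUE)) {
          invokeRestart("muffleWarning")
        }
      })
    quals <- as(Biostrings::quality(x), "IntegerList")
    lapply(seq_along(x), function(i) {
      quality_read(sub("\\s.*$", "", names(x)[i]),
                   as.character(x[[i]]), as.integer(quals[[i]]))
    })
  }
  fwd <- load_one(r1_path)
  rev <- load_one(r2_path)
  if (length(fwd) != length(rev)) {
    stop("R1 and R2 files hold different numbers of reads", call. = FALSE)
  }
  list(fwd = fwd, rev = rev)
}

#' Write quality reads as FASTQ (Phred+33)
#' @param reads List of [quality_read()]s.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(vapply(reads, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(reads, `[[`, character(1), "id")
  qstr <- vapply(reads, function(r) {
    intToUtf8(r$quals + 33L, multiple = FALSE)
  }, character(1))
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qstr))
  invisible(path)
}

#' Run the concatenation filter over a FASTQ pair batch
#'
#' @param pairs A list as returned by [read_fastq_pairs()], or the two
#'   paths given as `r1`/`r2`.
#' @param params A [qc_params()].
#' @return A data.frame with one row per pair: `id`, `status`, `ee_value`
#'   (NA when rejected short); attribute `"kept"` holds the concatenated
#'   [quality_read()]s.
#' @export
concat_filter_batch <- function(pairs, params = qc_params()) {
  stopifnot(is.list(pairs), all(c("fwd", "rev") %in% names(pairs)))
  outcomes <- mapply(function(f, r) concat_filter(f, r, params),
                     pairs$fwd, pairs$rev, SIMPLIFY = FALSE)
  df <- data.frame(
    id = vapply(pairs$fwd, `[[`, character(1), "id"),
    status = vapply(outcomes, `[[`, character(1), "status"),
    ee_value = vapply(outcomes, function(o) {
      if (is.null(o$ee_value)) NA_real_ else o$ee_value
    }, numeric(1)),
    stringsAsFactors = FALSE)
  attr(df, "kept") <- lapply(Filter(function(o) o$status == "kept", outcomes),
                             `[[`, "concatenated")
  df
}
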