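# Half-up rounding to `digits` decimals (printed tables use half-up, while
# base round() is banker's)
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Coverage of a single primer (pool) over a reference database
#'
#' A record counts as matched when it carries at least one exact full-length
#' binding site for any member of the pool.
#'
#' @param db A `reference_db`.
#' @param pool A [primer_pool()].
#' @return A one-row data.frame of class `"coverage_report"`: `subject`,
#'   `approach` (`"plain"`), `matched_count`, `database_size`, `percent`
#'   (to one decimal, half-up).
#' @export
primer_coverage <- function(db, pool) {
  if (length(db) == 0L) stop("reference database is empty", call. = FALSE)
  pool <- as_pool(pool)
  hit <- vapply(db$sequences, function(s) nrow(find_sites(s, pool)) > 0L, logical(1))
  coverage_report(pool$name, "plain", sum(hit), length(db))
}

coverage_report <- function(subject, approach, matched_count, database_size) {
  structure(data.frame(subject = subject, approach = approach,
                       matched_count = as.integer(matched_count),
                       database_size = as.integer(database_size),
                       percent = round_half_up(100 * matched_count / database_size, 1L),
                       stringsAsFactors = FALSE),
            class = c("coverage_report", "data.frame"))
}

# Per-record amplification verdicts for a pair; returns logical vector
pair_amplified <- function(db, fwd, rev, approach, slack = 100L) {
  vapply(seq_len(length(db)), function(i) {
    ex <- extract_amplicon(db$sequences[[i]], fwd, rev, mode = approach,
                           record_id = db$ids[i],
                           five_prime_complete = db$five_prime_complete[i],
                           slack = slack)
    ex$status %in% c("amplified", "assumed_amplified")
  }, logical(1))
}

#' Coverage of a primer pair over a reference database
#'
#' Counts records whose [extract_amplicon()] status is `amplified` — plus
#' `assumed_amplified` under the optimistic approach, which credits
#' 5'-truncated records carrying only the reverse site. Optimistic coverage
#' is therefore always at least the pessimistic one.
#'
#' @param db A `reference_db`.
#' @param fwd,rev Forward and reverse [primer_pool()]s.
#' @param approach `"pessimistic"`, `"optimistic"` or `"plain"`.
#' @param slack Truncation-heuristic slack (see [classify_truncation()]).
#' @return A one-row `"coverage_report"` data.frame.
#' @export
pair_coverage <- function(db, fwd, rev,
                          approach = c("pessimistic", "optimistic", "plain"),
                          slack = 100L) {
  if (length(db) == 0L) stop("reference database is empty", call. = FALSE)
  approach <- match.arg(approach)
  fwd <- as_pool(fwd); rev <- as_pool(rev)
  hit <- pair_amplified(db, fwd, rev, approach, slack)
  coverage_report(paste0(fwd$name, "-", rev$name), approach, sum(hit), length(db))
}

#' Per-genus coverage matrix for a set of primer pairs
#'
#' Cell (g, p) is the percentage of genus g's records amplified by pair p.
#' Records with an empty genus rank are aggregated under the reserved label
#' `"(unassigned)"` rather than dropped, so that the record-weighted column
#' mean always reconstructs the pair's overall coverage.
#'
#' @param db A `reference_db`.
#' @param pairs A list of pair specs, each a list with elements `fwd`, `rev`
#'   and optionally `approach` (default `"pessimistic"`) and `name`.
#' @param slack Truncation-heuristic slack.
#' @return A numeric matrix (class `"genus_coverage_matrix"`) with genus rows
#'   and primer-pair columns, values in [0, 100] at full precision (one
#'   decimal is applied when written as TSV); attribute `"genus_counts"`
#'   holds the per-genus record counts.
#' @export
genus_coverage_matrix <- function(db, pairs, slack = 100L) {
  if (length(db) == 0L) stop("reference database is empty", call. = FALSE)
  if (length(pairs) == 0L) stop("pair list is empty", call. = FALSE)
  genus <- vapply(db$lineages, function(l) l[["genus"]], character(1))
  genus[!nzchar(genus)] <- "(unassigned)"
  genera <- unique(genus)
  cols <- vapply(pairs, function(p) {
    if (!is.null(p$name)) p$name
    else paste0(as_pool(p$fwd)$name, "-", as_pool(p$rev)$name)
  }, character(1))
  mat <- matrix(NA_real_, nrow = length(genera), ncol = length(pairs),
                dimnames = list(genera, cols))
  counts <- as.vector(table(factor(genus, levels = genera)))
  for (j in seq_along(pairs)) {
    p <- pairs[[j]]
    approach <- if (is.null(p$approach)) "pessimistic" else p$approach
    hit <- pair_amplified(db, p$fwd, p$rev, approach, slack)
    agg <- tapply(hit, factor(genus, levels = genera), sum)
    # full precision kept here so record-weighted column means reconstruct
    # pair counts exactly; rounding to 1 decimal happens at write time
    mat[, j] <- 100 * as.vector(agg) / counts
  }
  structure(mat, genus_counts = stats::setNames(counts, genera),
            class = c("genus_coverage_matrix", class(mat)))
}

#' Fold-underrepresentation from sub-perfect PCR efficiency
#'
#' PCR amplification is exponential, so a template amplified with per-cycle
#' efficiency `e < 2` falls behind a perfectly amplified one by a factor of
#' `(2 / e)^cycles`. At efficiency 1.9x over 30 cycles a single copy appears
#' about 5-fold less abundant than one amplified at perfect efficiency.
#'
#' @param efficiency Per-cycle fold amplification, in (1, 2].
#' @param cycles Nonnegative integer number of cycles.
#' @return The fold-underrepresentation factor `(2 / efficiency)^cycles`.
#' @examples
#' amplification_bias(1.9, 30)  # ~4.66, i.e. ~5-fold
#' @export
amplification_bias <- function(efficiency, cycles) {
  if (!is.numeric(efficiency) || length(efficiency) != 1L ||
      efficiency <= 1 || efficiency > 2) {
    stop("efficiency must be a single value in (1, 2]", call. = FALSE)
  }
  if (!is.numeric(cycles) || length(cycles) != 1L || cycles < 0 ||
      cycles != floor(cycles)) {
    stop("cycles must be a single nonnegative integer", call. = FALSE)
  }
  (2 / efficiency)^cycles
}

#' Write a coverage report or genus matrix as TSV
#' @param x A `"coverage_report"` data.frame (possibly several rows bound
#'   together) or a `"genus_coverage_matrix"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_coverage_tsv <- function(x, path) {
  if (inherits(x, "genus_coverage_matrix")) {
    df <- data.frame(genus = rownames(x),
                     n_records = attr(x, "genus_counts")[rownames(x)],
                     as.data.frame(round_half_up(unclass(x), 1L),
                                   check.names = FALSE),
                     check.names = FALSE, row.names = NULL)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
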