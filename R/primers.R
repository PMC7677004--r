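# IUPAC nucleotide code table: code -> set of concrete bases
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                      R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                      B = "V", D = "H", H = "D", V = "B", N = "N")

check_iupac <- function(seq, what = "sequence") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad)) {
    stop("invalid IUPAC character '", chars[bad[1]], "' at position ", bad[1],
         " of ", what, " '", seq, "'", call. = FALSE)
  }
  chars
}

#' Construct a degenerate primer
#'
#' @param name Primer name, e.g. `"27f"`, `"534r"` (E. coli coordinate of the
#'   5' end plus orientation letter, by field convention).
#' @param sequence 5'->3' IUPAC string.
#' @param orientation `"forward"` or `"reverse"`.
#' @param expected_position Approximate E. coli 16S coordinate of the primer's
#'   5' end (optional; used by the 5'-truncation heuristic).
#' @return An object of class `"degenerate_primer"`.
#' @export
degenerate_primer <- function(name, sequence, orientation = c("forward", "reverse"),
                              expected_position = NA_integer_) {
  orientation <- match.arg(orientation)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("primer sequence must be nonempty", call. = FALSE)
  check_iupac(sequence, what = paste0("primer ", name))
  structure(list(name = name, sequence = sequence, orientation = orientation,
                 expected_position = as.integer(expected_position)),
            class = "degenerate_primer")
}

#' Construct a primer pool
#'
#' A pool is one or more degenerate primers of identical orientation used as a
#' single reagent (e.g. the 6-variant 27f pool).
#'
#' @param name Pool name.
#' @param members A list of [degenerate_primer()] objects, or a single one.
#' @return An object of class `"primer_pool"`.
#' @export
primer_pool <- function(name, members) {
  if (inherits(members, "degenerate_primer")) members <- list(members)
  if (length(members) == 0L) stop("primer pool must be nonempty", call. = FALSE)
  ok <- vapply(members, inherits, logical(1), "degenerate_primer")
  if (!all(ok)) stop("pool members must be degenerate_primer objects", call. = FALSE)
  orient <- unique(vapply(members, `[[`, character(1), "orientation"))
  if (length(orient) != 1L) {
    stop("all pool members must share one orientation", call. = FALSE)
  }
  structure(list(name = name, members = members, orientation = orient),
            class = "primer_pool")
}

#' @export
print.primer_pool <- function(x, ...) {
  cat("<primer_pool> ", x$name, " (", x$orientation, ", ",
      length(x$members), " member(s))\n", sep = "")
  for (m in x$members) {
    cat("  ", m$sequence, "  [degeneracy ", primer_degeneracy(m), "]\n", sep = "")
  }
  invisible(x)
}

as_pool <- function(x) {
  if (inherits(x, "primer_pool")) return(x)
  if (inherits(x, "degenerate_primer")) return(primer_pool(x$name, list(x)))
  stop("expected a primer_pool or degenerate_primer", call. = FALSE)
}

#' Degeneracy of a primer (number of concrete variants)
#' @param primer A [degenerate_primer()].
#' @return Product of per-position IUPAC cardinalities.
#' @export
primer_degeneracy <- function(primer) {
  chars <- check_iupac(primer$sequence)
  prod(vapply(IUPAC_SETS[chars], length, integer(1)))
}

#' Expand a degenerate primer into all concrete variants
#'
#' @param primer A [degenerate_primer()] or an IUPAC string.
#' @return Character vector of every A/C/G/T sequence consistent with the
#'   degenerate codes; its length equals [primer_degeneracy()].
#' @examples
#' length(expand_degenerate("AGAGTTTGATYMTGGCTCAG"))  # 4
#' @export
expand_degenerate <- function(primer) {
  seq <- if (inherits(primer, "degenerate_primer")) primer$sequence else toupper(primer)
  chars <- check_iupac(seq)
  sets <- IUPAC_SETS[chars]
  out <- ""
  for (s in sets) {
    out <- as.vector(outer(out, s, paste0))
  }
  sort(out)
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' Applies the standard IUPAC complement (Y<->R, B<->V, ...) and reverses.
#' An involution: `reverse_complement(reverse_complement(x)) == x`.
#'
#' @param seq IUPAC string.
#' @return The reverse complement, same alphabet.
#' @export
reverse_complement <- function(seq) {
  check_iupac(toupper(seq))
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

# Template letters allowed at a primer position: all IUPAC codes whose base
# set is a subset of the primer code's set (template N matches only primer N).
template_class <- function(code) {
  pset <- IUPAC_SETS[[code]]
  ok <- vapply(IUPAC_SETS, function(ts) all(ts %in% pset), logical(1))
  names(IUPAC_SETS)[ok]
}

primer_regex <- function(seq) {
  chars <- check_iupac(seq)
  paste(vapply(chars, function(code) {
    cls <- template_class(code)
    if (length(cls) == 1L) cls else paste0("[", paste(cls, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# All 0-based start positions of `pattern_regex` in `template`, including
# overlapping occurrences (lookahead trick).
regex_starts <- function(template, pattern_regex) {
  m <- gregexpr(paste0("(?=", pattern_regex, ")"), template, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

# Independent position-by-position scanner used as the dual implementation
# route; results must be identical to the regex route.
scan_starts <- function(template, primer_seq) {
  tchars <- strsplit(template, "", fixed = TRUE)[[1]]
  pchars <- check_iupac(primer_seq)
  k <- length(pchars)
  n <- length(tchars)
  if (n < k) return(integer(0))
  allowed <- lapply(pchars, template_class)
  hits <- integer(0)
  for (s in 0:(n - k)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!tchars[s + j] %in% allowed[[j]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

#' Locate exact full-length primer binding sites on a template
#'
#' Searches the forward-oriented template for exact, full-length matches to
#' any member of the pool. Forward pools are searched as written; reverse
#' pools are searched as the reverse complement of each member, with site
#' coordinates still reported on the forward strand. A template position
#' matches a primer position only when the template code's base set is a
#' subset of the primer code's set, so low-quality template Ns never match a
#' concrete primer base. No mismatches and no partial overlap at the
#' sequence ends are allowed.
#'
#' @param sequence Template sequence (forward-oriented, IUPAC).
#' @param pool A [primer_pool()] (or single [degenerate_primer()]).
#' @param record_id Identifier copied into the result.
#' @param engine `"regex"` (default) or `"scan"`; two independent matching
#'   routes that must agree.
#' @return A data.frame of binding sites with columns `record_id`, `start`,
#'   `end` (0-based half-open on the forward strand), `matched_variant` (the
#'   concrete template subsequence), `primer_name`, `orientation`, sorted by
#'   `start`. Zero rows when there is no match.
#' @export
find_sites <- function(sequence, pool, record_id = "", engine = c("regex", "scan")) {
  engine <- match.arg(engine)
  pool <- as_pool(pool)
  sequence <- toupper(sequence)
  hits <- list()
  for (m in pool$members) {
    query <- if (pool$orientation == "reverse") reverse_complement(m$sequence) else m$sequence
    starts <- if (engine == "regex") {
      regex_starts(sequence, primer_regex(query))
    } else {
      scan_starts(sequence, query)
    }
    if (length(starts)) {
      hits[[length(hits) + 1L]] <- data.frame(
        record_id = record_id,
        start = starts,
        end = starts + nchar(query),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(record_id = character(0), start = integer(0),
                      end = integer(0), matched_variant = character(0),
                      primer_name = character(0), orientation = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  out$matched_variant <- substring(sequence, out$start + 1L, out$end)
  out$primer_name <- pool$name
  out$orientation <- pool$orientation
  rownames(out) <- NULL
  out
}

#' Read a primer configuration table
#'
#' Tab-separated file with columns `name`, `pool`, `orientation`, `sequence`,
#' `expected_position`. Rows sharing a `pool` label form one pool. The
#' configuration shipped with the package
#' (`system.file("extdata", "primers.tsv", package = "ampliscreen")`) holds
#' the primer sets commonly used for vaginal-microbiome 16S profiling,
#' including the 6-variant 27f pool and the extended-degeneracy 515r/534r
#' variants that add Chlamydia coverage.
#'
#' @param path Path to the TSV file.
#' @return A named list of [primer_pool()] objects.
#' @export
read_primer_config <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    check.names = FALSE)
  needed <- c("name", "pool", "orientation", "sequence")
  if (!all(needed %in% names(tab))) {
    stop("primer config needs columns: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  if (!"expected_position" %in% names(tab)) tab$expected_position <- NA
  pools <- list()
  for (p in unique(tab$pool)) {
    rows <- tab[tab$pool == p, , drop = FALSE]
    members <- lapply(seq_len(nrow(rows)), function(i) {
      degenerate_primer(rows$name[i], rows$sequence[i], rows$orientation[i],
                        expected_position = suppressWarnings(
                          as.integer(rows$expected_position[i])))
    })
    pools[[p]] <- primer_pool(p, members)
  }
  pools
}

# Expected E. coli coordinate of a pool's 5' end (first non-NA member value)
pool_expected_position <- function(pool) {
  pos <- vapply(pool$members, `[[`, integer(1), "expected_position")
  pos <- pos[!is.na(pos)]
  if (!length(pos)) NA_integer_ else pos[1]
}
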