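#' Construct a ranked annotation
#'
#' An annotation is a 7-rank lineage, optionally with a set of candidate
#' species epithets for reads that classifiers could only place in a
#' multi-species group (e.g. "Lactobacillus crispatus/gasseri/jensenii").
#' A singleton candidate set is equivalent to a filled species rank and is
#' normalised to one.
#'
#' @param lineage A lineage from [parse_lineage()], or a lineage string.
#' @param species_candidates Optional character vector of species epithets;
#'   requires a filled genus rank.
#' @return An object of class `"ranked_annotation"`.
#' @export
ranked_annotation <- function(lineage, species_candidates = NULL) {
  if (is.character(lineage) && !inherits(lineage, "lineage")) {
    lineage <- if (length(lineage) == 7L) new_lineage(lineage) else parse_lineage(lineage)
  }
  lin <- unclass(lineage)
  if (!is.null(species_candidates)) {
    species_candidates <- sort(unique(as.character(species_candidates)))
    if (length(species_candidates) == 0L) species_candidates <- NULL
  }
  if (!is.null(species_candidates)) {
    if (!nzchar(lin[["genus"]])) {
      stop("species candidates require a filled genus rank", call. = FALSE)
    }
    if (length(species_candidates) == 1L) {
      lin[["species"]] <- species_candidates
      species_candidates <- NULL
    } else {
      lin[["species"]] <- ""
    }
  }
  structure(list(lineage = new_lineage(lin),
                 species_candidates = species_candidates),
            class = "ranked_annotation")
}

#' Parse "Genus epi1/epi2" annotation notation
#'
#' @param lineage_string Delimited lineage string; the species field may hold
#'   a slash-separated candidate set.
#' @param delim Rank delimiter.
#' @return A [ranked_annotation()].
#' @export
parse_annotation <- function(lineage_string, delim = ";") {
  lin <- parse_lineage(lineage_string, delim = delim)
  sp <- lin[["species"]]
  if (grepl("/", sp, fixed = TRUE)) {
    cands <- strsplit(sp, "/", fixed = TRUE)[[1]]
    lin[["species"]] <- ""
    ranked_annotation(new_lineage(unclass(lin)), species_candidates = cands)
  } else {
    ranked_annotation(lin)
  }
}

#' @export
print.ranked_annotation <- function(x, ...) {
  cat("<ranked_annotation> ", format_annotation(x), "\n", sep = "")
  invisible(x)
}

#' Serialize a ranked annotation (candidate sets as "epi1/epi2", sorted)
#' @param a A [ranked_annotation()].
#' @param delim Rank delimiter.
#' @return A single string.
#' @export
format_annotation <- function(a, delim = ";") {
  lin <- unclass(a$lineage)
  if (!is.null(a$species_candidates)) {
    lin[["species"]] <- paste(a$species_candidates, collapse = "/")
  }
  d <- if (any(nzchar(lin))) max(which(nzchar(lin))) else 0L
  paste(lin[seq_len(d)], collapse = delim)
}

# species evidence: candidate set if present, else singleton from the
# species rank, else NULL
species_evidence <- function(a) {
  if (!is.null(a$species_candidates)) return(a$species_candidates)
  sp <- a$lineage[["species"]]
  if (nzchar(sp)) sp else NULL
}

#' Consensus of forward- and reverse-read annotations
#'
#' Reconciles two potentially different annotations of the same amplicon by
#' three rules: (i) if any rank where both are annotated disagrees, keep
#' only the lowest common ancestor (the deepest rank down to which all
#' overlapping annotations agree); (ii) if one annotation extends the other
#' and they agree wherever both are annotated, keep the more detailed one;
#' (iii) at species level, when both carry candidate sets under the same
#' genus, keep the intersection — an empty intersection counts as a species
#' disagreement and falls back to genus level. The result is independent of
#' argument order, and `consensus_annotation(a, a) == a`.
#'
#' @param a,b [ranked_annotation()] objects.
#' @return A [ranked_annotation()].
#' @examples
#' base <- "Bacteria;Firmicutes;Bacilli;Lactobacillales;Lactobacillaceae;Lactobacillus;"
#' f <- parse_annotation(paste0(base, "crispatus/gasseri/jensenii"))
#' r <- parse_annotation(paste0(base, "gasseri/jensenii/longum"))
#' format_annotation(consensus_annotation(f, r))  # "...;gasseri/jensenii"
#' @export
consensus_annotation <- function(a, b) {
  la <- unclass(a$lineage); lb <- unclass(b$lineage)
  out <- character(7L)
  # ranks 1..6: agree / one-sided / conflict
  for (k in 1:6) {
    fa <- nzchar(la[[k]]); fb <- nzchar(lb[[k]])
    if (fa && fb) {
      if (identical(la[[k]], lb[[k]])) out[k] <- la[[k]]
      else return(ranked_annotation(new_lineage(c(out[seq_len(k - 1L)],
                                                  rep("", 8L - k)))))
    } else if (fa) out[k] <- la[[k]]
    else if (fb) out[k] <- lb[[k]]
    else out[k] <- ""
  }
  # holes cannot survive: clear anything after the first empty rank
  first_empty <- match(TRUE, !nzchar(out[1:6]), nomatch = 7L)
  out[first_empty:7L] <- ""
  if (first_empty <= 6L) {
    return(ranked_annotation(new_lineage(out)))
  }
  # species level (genus agreed and is filled if we get here with evidence)
  ea <- species_evidence(a); eb <- species_evidence(b)
  if (is.null(ea) && is.null(eb)) {
    return(ranked_annotation(new_lineage(out)))
  }
  if (is.null(ea) || is.null(eb)) {
    keep <- if (is.null(ea)) eb else ea
    return(ranked_annotation(new_lineage(out), species_candidates = keep))
  }
  inter <- intersect(ea, eb)
  if (length(inter) == 0L) {
    # null intersection: species-level disagreement, fall back to genus
    return(ranked_annotation(new_lineage(out)))
  }
  ranked_annotation(new_lineage(out), species_candidates = inter)
}

#' Depth of a ranked annotation
#'
#' Number of filled ranks, 0..7. A multi-species candidate set leaves the
#' species rank open and counts as depth 6 (the annotation is resolved to
#' genus, with species ambiguity flagged); a singleton set counts as 7.
#'
#' @param a A [ranked_annotation()].
#' @return Integer in 0..7, with attribute `"ambiguous_species"` TRUE when a
#'   multi-species candidate set is present.
#' @export
annotation_depth <- function(a) {
  structure(lineage_depth(a$lineage),
            ambiguous_species = !is.null(a$species_candidates))
}

#' Score a predicted annotation against a known true lineage
#'
#' @param pred A [ranked_annotation()].
#' @param truth A full 7-rank lineage (species filled).
#' @return Character vector of 7 per-rank verdicts: `"correct"` (filled and
#'   equal to truth), `"incorrect"` (filled and unequal), `"unannotated"`
#'   (empty). A non-singleton species candidate set containing the true
#'   epithet scores `"ambiguous"`; one not containing it, `"incorrect"`.
#' @export
score_against_truth <- function(pred, truth) {
  lt <- unclass(truth)
  if (any(!nzchar(lt))) stop("truth lineage must be fully specified to species",
                             call. = FALSE)
  lp <- unclass(pred$lineage)
  verdict <- character(7L)
  for (k in 1:6) {
    verdict[k] <- if (!nzchar(lp[[k]])) "unannotated"
                  else if (identical(lp[[k]], lt[[k]])) "correct" else "incorrect"
  }
  if (!is.null(pred$species_candidates)) {
    verdict[7] <- if (lt[["species"]] %in% pred$species_candidates) "ambiguous"
                  else "incorrect"
  } else if (!nzchar(lp[["species"]])) {
    verdict[7] <- "unannotated"
  } else {
    verdict[7] <- if (identical(lp[["species"]], lt[["species"]])) "correct"
                  else "incorrect"
  }
  stats::setNames(verdict, RANK_NAMES)
}

#' Aggregate per-rank accuracy over many scored annotations
#'
#' @param preds List of [ranked_annotation()] predictions.
#' @param truths List of true lineages, same length.
#' @return A list of class `"accuracy_summary"`: `per_rank` (7 x 4 count
#'   matrix of correct/incorrect/unannotated/ambiguous) and
#'   `deepest_correct` (histogram over 0..7 of the deepest rank down to
#'   which each prediction is entirely correct).
#' @export
summarize_accuracy <- function(preds, truths) {
  stopifnot(length(preds) == length(truths))
  levs <- c("correct", "incorrect", "unannotated", "ambiguous")
  per_rank <- matrix(0L, nrow = 7L, ncol = 4L,
                     dimnames = list(RANK_NAMES, levs))
  deepest <- integer(length(preds))
  for (i in seq_along(preds)) {
    v <- score_against_truth(preds[[i]], truths[[i]])
    for (k in 1:7) per_rank[k, v[k]] <- per_rank[k, v[k]] + 1L
    ok <- v == "correct"
    deepest[i] <- if (!ok[1]) 0L else max(which(cumsum(!ok) == 0L))
  }
  structure(list(per_rank = per_rank,
                 deepest_correct = table(factor(deepest, levels = 0:7))),
            class = "accuracy_summary")
}

#' @export
print.accuracy_summary <- function(x, ...) {
  cat("<accuracy_summary>\n")
  print(x$per_rank)
  cat("deepest correct rank:\n")
  print(x$deepest_correct)
  invisible(x)
}

#' Read annotations from TSV (read_id, lineage string, optional candidates)
#' @param path TSV with columns `read_id`, `lineage`; the species field may
#'   use the `epi1/epi2` candidate notation.
#' @return Named list of [ranked_annotation()] keyed by read id.
#' @export
read_annotations <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    check.names = FALSE)
  if (!all(c("read_id", "lineage") %in% names(tab))) {
    stop("annotation table needs columns 'read_id' and 'lineage'", call. = FALSE)
  }
  out <- lapply(tab$lineage, parse_annotation)
  names(out) <- tab$read_id
  out
}
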