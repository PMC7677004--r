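#' @importFrom methods as is
#' @importFrom utils read.delim write.table head tail
#' @importFrom stats setNames
NULL

RANK_NAMES <- c("domain", "phylum", "class", "order", "family", "genus", "species")

#' Parse a delimited lineage string into a ranked lineage
#'
#' Splits a SILVA-style lineage string into the seven canonical ranks
#' (domain, phylum, class, order, family, genus, species), right-padding
#' missing ranks with empty strings. Surrounding whitespace is stripped
#' from each rank label.
#'
#' @param text Lineage string, e.g.
#'   `"Bacteria;Firmicutes;Bacilli;Lactobacillales;Lactobacillaceae;Lactobacillus;crispatus"`.
#' @param delim Rank delimiter (default `";"`).
#' @return A named character vector of length 7 (class `"lineage"`); empty
#'   strings mark unannotated ranks. Once a rank is empty, all deeper ranks
#'   are empty.
#' @examples
#' parse_lineage("Bacteria;Firmicutes")
#' @export
parse_lineage <- function(text, delim = ";") {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  fields <- if (nzchar(text)) strsplit(text, delim, fixed = TRUE)[[1]] else character(0)
  fields <- trimws(fields)
  if (length(fields) > 7L) {
    stop("lineage string has ", length(fields), " fields; at most 7 ranks are allowed: ",
         text, call. = FALSE)
  }
  ranks <- c(fields, rep("", 7L - length(fields)))
  # normalise internal gaps: everything after the first empty rank is cleared
  first_empty <- match(TRUE, !nzchar(ranks), nomatch = 8L)
  if (first_empty <= 7L) ranks[first_empty:7L] <- ""
  new_lineage(ranks)
}

new_lineage <- function(ranks) {
  structure(setNames(as.character(ranks), RANK_NAMES), class = "lineage")
}

#' Number of filled ranks of a lineage
#' @param lineage A lineage vector as returned by [parse_lineage()].
#' @return Integer in 0..7.
#' @export
lineage_depth <- function(lineage) {
  sum(nzchar(unclass(lineage)))
}

#' Serialize a lineage back to its delimited string form
#' @param lineage A lineage vector.
#' @param delim Rank delimiter.
#' @return A single string; trailing empty ranks are dropped.
#' @export
format_lineage <- function(lineage, delim = ";") {
  r <- unclass(lineage)
  paste(r[seq_len(lineage_depth(lineage))], collapse = delim)
}

#' Read a 16S reference database (FASTA + taxonomy table)
#'
#' Loads reference sequences from FASTA and joins them to a tab-separated
#' taxonomy table with columns `id`, `lineage`, and optionally
#' `five_prime_complete` (values `complete`/`truncated`). Records missing the
#' metadata column get the flag `"unknown"`. Sequences are upper-cased and U
#' is mapped to T, so mixed rRNA/DNA conventions read identically.
#'
#' @param fasta_path Path to the FASTA file of 16S sequences.
#' @param taxonomy_path Path to the tab-separated taxonomy table.
#' @param delim Rank delimiter inside the lineage strings.
#' @return An object of class `"reference_db"`: a list with `ids`,
#'   `sequences` (named character), `lineages` (list of lineage vectors),
#'   `five_prime_complete` (character: complete/truncated/unknown) and
#'   `source_label`.
#' @export
read_reference_db <- function(fasta_path, taxonomy_path, delim = ";") {
  # read as raw strings so that U/lowercase reach normalize_sequence intact
  # (readDNAStringSet would silently drop letters outside the DNA alphabet)
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", fasta_path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  tax <- read.delim(taxonomy_path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
  if (nrow(tax) == 0L) stop("empty taxonomy table: ", taxonomy_path, call. = FALSE)
  if (!all(c("id", "lineage") %in% names(tax))) {
    stop("taxonomy table must have columns 'id' and 'lineage'", call. = FALSE)
  }
  if (anyDuplicated(tax$id)) {
    stop("duplicate taxonomy ids: ",
         paste(unique(tax$id[duplicated(tax$id)]), collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(ids, tax$id)
  if (length(missing)) {
    stop("FASTA id(s) missing from taxonomy table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tax <- tax[match(ids, tax$id), , drop = FALSE]
  five <- if ("five_prime_complete" %in% names(tax)) {
    f <- tax$five_prime_complete
    f[is.na(f) | !nzchar(f)] <- "unknown"
    bad <- setdiff(unique(f), c("complete", "truncated", "unknown"))
    if (length(bad)) stop("invalid five_prime_complete value(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    f
  } else rep("unknown", length(ids))
  sequences <- normalize_sequence(as.character(seqs))
  names(sequences) <- ids
  lineages <- lapply(tax$lineage, parse_lineage, delim = delim)
  new_reference_db(ids, sequences, lineages, five,
                   source_label = basename(fasta_path))
}

normalize_sequence <- function(x) {
  x <- chartr("u", "t", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", x)
  if (any(bad)) {
    stop("sequence(s) contain non-IUPAC characters: record index ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  x
}

new_reference_db <- function(ids, sequences, lineages, five_prime_complete,
                             source_label = "") {
  stopifnot(length(ids) == length(sequences),
            length(ids) == length(lineages),
            length(ids) == length(five_prime_complete))
  if (any(!nzchar(sequences))) stop("empty sequence in reference database", call. = FALSE)
  structure(list(ids = as.character(ids),
                 sequences = sequences,
                 lineages = lineages,
                 five_prime_complete = five_prime_complete,
                 source_label = source_label),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat("<reference_db> ", length(x$ids), " records",
      if (nzchar(x$source_label)) paste0(" [", x$source_label, "]"), "\n", sep = "")
  genera <- vapply(x$lineages, function(l) l[["genus"]], character(1))
  genera <- genera[nzchar(genera)]
  if (length(genera)) {
    tab <- sort(table(genera), decreasing = TRUE)
    cat("  genera: ", paste(head(names(tab), 6L), collapse = ", "),
        if (length(tab) > 6L) ", ...", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.reference_db <- function(x) length(x$ids)

#' Write a reference database back to FASTA + taxonomy files
#'
#' Inverse of [read_reference_db()]: re-reading the two files yields an
#' identical database (round-trip contract).
#'
#' @param db A `reference_db`.
#' @param fasta_path,taxonomy_path Output paths.
#' @param delim Rank delimiter for lineage strings.
#' @return Invisibly, `db`.
#' @export
write_reference_db <- function(db, fasta_path, taxonomy_path, delim = ";") {
  seqs <- Biostrings::DNAStringSet(db$sequences)
  names(seqs) <- db$ids
  Biostrings::writeXStringSet(seqs, fasta_path)
  tax <- data.frame(id = db$ids,
                    lineage = vapply(db$lineages, format_lineage, character(1),
                                     delim = delim),
                    five_prime_complete = db$five_prime_complete,
                    stringsAsFactors = FALSE)
  write.table(tax, taxonomy_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(db)
}

#' Read a taxon list (name + optional rank)
#'
#' @param path Tab-separated file with column `name` and optional columns
#'   `rank` and `note`.
#' @return A data.frame with columns `name`, `rank` (NA when unstated) and
#'   `note`.
#' @export
read_taxon_list <- function(path) {
  tl <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   check.names = FALSE)
  if (!"name" %in% names(tl)) stop("taxon list must have a 'name' column", call. = FALSE)
  if (!"rank" %in% names(tl)) tl$rank <- NA_character_
  tl$rank[!nzchar(tl$rank) | is.na(tl$rank)] <- NA_character_
  if (!"note" %in% names(tl)) tl$note <- ""
  if (any(!nzchar(tl$name))) stop("empty taxon name in taxon list", call. = FALSE)
  if (anyDuplicated(tolower(tl$name))) {
    stop("duplicate taxon names (case-insensitive) in taxon list", call. = FALSE)
  }
  tl[, c("name", "rank", "note")]
}

#' Subset a reference database by a taxon list
#'
#' Keeps every record whose lineage contains any listed taxon name at its
#' stated rank; when no rank is stated for an entry, any rank may match.
#' Matching is case-insensitive. Record order is preserved.
#'
#' @param db A `reference_db`.
#' @param taxa A data.frame as returned by [read_taxon_list()], or a
#'   character vector of names (matched at any rank).
#' @return A `reference_db` with the matching records; a warning is raised
#'   (not an error) when no record matches.
#' @export
subset_by_taxa <- function(db, taxa) {
  if (is.character(taxa)) {
    taxa <- data.frame(name = taxa, rank = NA_character_, stringsAsFactors = FALSE)
  }
  if (nrow(taxa) == 0L) stop("taxon list is empty", call. = FALSE)
  bad_rank <- !is.na(taxa$rank) & !(taxa$rank %in% RANK_NAMES)
  if (any(bad_rank)) stop("unknown rank(s) in taxon list: ",
                          paste(unique(taxa$rank[bad_rank]), collapse = ", "),
                          call. = FALSE)
  keep <- vapply(db$lineages, function(l) {
    lr <- tolower(unclass(l))
    any(vapply(seq_len(nrow(taxa)), function(i) {
      nm <- tolower(taxa$name[i])
      if (is.na(taxa$rank[i])) nm %in% lr else identical(lr[[taxa$rank[i]]], nm)
    }, logical(1)))
  }, logical(1))
  if (!any(keep)) warning("no record matches the taxon list", call. = FALSE)
  new_reference_db(db$ids[keep], db$sequences[keep], db$lineages[keep],
                   db$five_prime_complete[keep], db$source_label)
}
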