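DEFAULT_TRIAXIAL_TAXA <- c("Lactobacillus crispatus", "Lactobacillus iners",
                           "Gardnerella vaginalis")

#' Normalize three-taxon abundances onto the 2-simplex
#'
#' The triaxial representation used to compare sequencing-derived profiles
#' against qPCR: the abundances of the three key taxa (by default
#' L. crispatus, L. iners, G. vaginalis) are divided by their sum so the
#' profile sums to 1.
#'
#' @param raw Numeric vector of nonnegative abundances, one per taxon.
#' @param taxa Taxon names, same length and order as `raw`.
#' @param sample_id Used in the all-zero error message.
#' @return A named numeric vector of class `"triaxial_profile"` summing
#'   to 1.
#' @examples
#' normalize_three_taxa(c(2, 1, 1))
#' @export
normalize_three_taxa <- function(raw, taxa = DEFAULT_TRIAXIAL_TAXA,
                                 sample_id = "") {
  stopifnot(is.numeric(raw), length(raw) == length(taxa))
  if (any(raw < 0)) stop("abundances must be nonnegative", call. = FALSE)
  total <- sum(raw)
  if (total == 0) {
    stop("all three taxa are zero for sample '", sample_id,
         "'; the profile cannot be placed on the simplex", call. = FALSE)
  }
  structure(stats::setNames(raw / total, taxa), class = "triaxial_profile")
}

#' Manhattan distance between two triaxial profiles
#'
#' Sum of absolute coordinate differences. Identical profiles give 0; for
#' two nonnegative profiles each summing to 1 the attainable maximum is 2.
#'
#' @param p,q `"triaxial_profile"` vectors over the same taxa in the same
#'   order.
#' @return Nonnegative float in [0, 2].
#' @export
manhattan_distance <- function(p, q) {
  if (length(p) != length(q) || !identical(names(p), names(q))) {
    stop("profiles must cover the same taxa in the same order", call. = FALSE)
  }
  sum(abs(unclass(p) - unclass(q)))
}

#' Compare method profiles against qPCR reference profiles
#'
#' Both sides are given as long-format tables (`sample_id`, `method` for the
#' query side, `taxon`, `abundance`); each (sample, method) profile and its
#' reference sample profile are normalized to the simplex and their
#' Manhattan distance computed.
#'
#' @param profiles Data.frame with columns `sample_id`, `method`, `taxon`,
#'   `abundance`.
#' @param reference Data.frame with columns `sample_id`, `taxon`,
#'   `abundance` (e.g. qPCR quantities).
#' @param taxa Taxon names defining the simplex axes and their order.
#' @return Data.frame with columns `sample_id`, `method`, `manhattan`,
#'   sorted by sample then method.
#' @export
batch_compare <- function(profiles, reference, taxa = DEFAULT_TRIAXIAL_TAXA) {
  need_p <- c("sample_id", "method", "taxon", "abundance")
  need_r <- c("sample_id", "taxon", "abundance")
  if (!all(need_p %in% names(profiles))) {
    stop("profiles table needs columns: ", paste(need_p, collapse = ", "), call. = FALSE)
  }
  if (!all(need_r %in% names(reference))) {
    stop("reference table needs columns: ", paste(need_r, collapse = ", "), call. = FALSE)
  }
  pull <- function(tab, sid, method = NULL, label) {
    rows <- tab$sample_id == sid
    if (!is.null(method)) rows <- rows & tab$method == method
    sub <- tab[rows, , drop = FALSE]
    vals <- vapply(taxa, function(tx) {
      hit <- sub$taxon == tx
      if (!any(hit)) 0 else sum(as.numeric(sub$abundance[hit]))
    }, numeric(1))
    normalize_three_taxa(vals, taxa, sample_id = paste0(label, ":", sid))
  }
  keys <- unique(profiles[, c("sample_id", "method")])
  keys <- keys[order(keys$sample_id, keys$method), , drop = FALSE]
  missing_ref <- setdiff(unique(keys$sample_id), unique(reference$sample_id))
  if (length(missing_ref)) {
    stop("no reference profile for sample(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  manhattan <- vapply(seq_len(nrow(keys)), function(i) {
    p <- pull(profiles, keys$sample_id[i], keys$method[i], "profiles")
    q <- pull(reference, keys$sample_id[i], NULL, "reference")
    manhattan_distance(p, q)
  }, numeric(1))
  data.frame(sample_id = keys$sample_id, method = keys$method,
             manhattan = manhattan, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Read a long-format abundance table from TSV
#' @param path TSV with columns `sample_id`, optionally `method`, `taxon`,
#'   `abundance`.
#' @return A data.frame.
#' @export
read_abundance_tsv <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  tab$abundance <- as.numeric(tab$abundance)
  tab
}
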