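# Shared fixtures and independent brute-force oracles for the suite.
# The oracles deliberately re-derive results from first principles and never
# call the implementation paths they check.

shipped_pools <- function() {
  read_primer_config(system.file("extdata", "primers.tsv", package = "ampliscreen"))
}

# --- independent IUPAC table (oracle-side copy) ------------------------------
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# recursive enumeration of concrete variants (for primers <= 12 nt)
oracle_expand <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  stopifnot(length(chars) <= 12L)
  out <- ""
  for (ch in chars) {
    out <- unlist(lapply(out, function(p) paste0(p, ORACLE_IUPAC[[ch]])))
  }
  sort(out)
}

# --- brute-force 3' quality trimming oracle ----------------------------------
# try every possible suffix cut and keep the one with the maximal positive
# score sum(q_cutoff - Q) over the removed bases; ties remove more
oracle_truncate_keep <- function(quals, q_cutoff = 15L) {
  n <- length(quals)
  best_cut <- 0L; best_score <- 0
  for (cut in seq_len(n)) {
    score <- sum(q_cutoff - quals[(n - cut + 1L):n])
    if (score > best_score || (score == best_score && score > 0)) {
      best_score <- score; best_cut <- cut
    }
  }
  n - best_cut
}

# --- brute-force concatenation filter oracle ---------------------------------
oracle_concat_status <- function(fq, rq, q_cutoff = 15L, trim_len = 270L,
                                 max_ee = 4) {
  kf <- oracle_truncate_keep(fq, q_cutoff)
  kr <- oracle_truncate_keep(rq, q_cutoff)
  if (kf < trim_len || kr < trim_len) return("rejected_short")
  ee <- sum(10^(-fq[seq_len(trim_len)] / 10)) +
        sum(10^(-rq[seq_len(trim_len)] / 10))
  if (ee > max_ee) "rejected_ee" else "kept"
}

# --- simplex grid of three-part compositions ---------------------------------
simplex_grid <- function(steps = 10L) {
  out <- list()
  for (i in 0:steps) for (j in 0:(steps - i)) {
    out[[length(out) + 1L]] <- c(i, j, steps - i - j) / steps
  }
  out
}

# --- random ranked annotations for property tests ----------------------------
# labels per rank drawn from a tiny vocabulary so that agreements, conflicts
# and prefix relations all occur with useful frequency
random_annotation <- function() {
  labels <- list(c("Bacteria"),
                 c("Firmicutes", "Actinobacteria"),
                 c("Bacilli", "Clostridia"),
                 c("Lactobacillales", "Bifidobacteriales"),
                 c("Lactobacillaceae", "Bifidobacteriaceae"),
                 c("Lactobacillus", "Gardnerella"),
                 c("crispatus", "iners", "gasseri", "jensenii"))
  depth <- sample(0:7, 1L)
  ranks <- character(7L)
  for (k in seq_len(depth)) ranks[k] <- sample(labels[[k]], 1L)
  cands <- NULL
  if (depth >= 6L && runif(1) < 0.4) {
    ranks[7] <- ""
    cands <- sample(labels[[7]], sample(1:3, 1L))
  }
  ranked_annotation(ranks, species_candidates = cands)
}

annotation_equal <- function(a, b) {
  identical(format_annotation(a), format_annotation(b))
}
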