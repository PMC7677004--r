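---
title: "Methods: primer coverage, in-silico PCR, consensus annotation and read QC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: primer coverage, in-silico PCR, consensus annotation and read QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliscreen)
```

# Scope

`ampliscreen` evaluates degenerate 16S rRNA primer pairs and downstream
amplicon-processing choices *in silico*, against a taxonomically annotated
full-length reference database. It answers four questions:

1. What fraction of the database does a primer, or a primer pair, amplify
   under exact full-length matching?
2. Given an amplicon, should the two sequencing reads be merged or kept
   paired, and what do the simulated reads look like?
3. When the forward and reverse reads of a pair receive conflicting
   taxonomic annotations, what is the defensible consensus?
4. How far is a three-taxon (triaxial) community profile from a reference
   (e.g. qPCR) profile?

It also ships a deterministic synthetic-fixture generator so that every one
of these operations can be tested against a planted, exactly known truth.

# Degenerate-primer site search

A primer is a string over the IUPAC alphabet; a pool is a set of such
strings used as one reagent. A primer letter matches a template letter when
the template letter's base set is a **subset** of the primer letter's base
set. This is deliberate: a template `N` is an unknown base, so only a primer
`N` (which tolerates every base) is guaranteed to bind it, whereas a primer
`Y` matches template `C`, `T` and `Y` but not template `N`. Matching is
exact over the primer's full length — no mismatches, no partial anchoring.

Reverse primers are stored oligo-sense and searched as their reverse
complement on the forward strand, so all reported coordinates are 0-based,
half-open, forward-strand intervals.

Two independent engines implement the same semantics — a regular-expression
engine (character classes inside a lookahead, so overlapping starts are all
found) and a position-by-position scanner — and the test suite cross-checks
them on random templates. `find_sites()` defaults to the regex engine.

# Pair coverage: pessimistic and optimistic

A record counts as amplified by a pair when it has at least one forward site
and one reverse site with a positive inner span between the outermost pair
of sites (5′-most forward, 3′-most reverse). That is the **pessimistic**
accounting.

Reference databases truncate many records at the 5′ end, clipping the
forward-primer locus out of the record even though the gene itself would be
amplified. The **optimistic** accounting therefore additionally credits
records that (a) have a reverse site, (b) lack a forward site, and (c) are
5′-truncated. Truncation is taken from the database's
`five_prime_complete` flag when present; otherwise a heuristic is used: the
number of bases upstream of the reverse site is compared against the
expected distance implied by the primers' annotated reference coordinates,
with a slack of 100 bases. The slack absorbs real-world indel variation in
the gene without letting full-length non-matching records masquerade as
truncated ones.

Per-genus coverage matrices keep full-precision percentages internally so
that record-weighted column means reconstruct pair counts exactly;
half-up rounding to one decimal happens only when a table is written.

The cost of imperfect amplification is summarized by
`amplification_bias(efficiency, cycles)` $= (2/e)^c$, the fold
underrepresentation of a template amplified at per-cycle efficiency $e \in
(1, 2]$ relative to a perfectly amplified one after $c$ cycles:

```{r bias}
amplification_bias(1.9, 30)
```

i.e. roughly five-fold underrepresentation from a seemingly mild 1.9×
per-cycle efficiency over 30 cycles.

# Read simulation: merged, paired, or both

Simulation parameters default to `read_len = 250`, `merge_threshold = 500`
and `near_window = 10`. For an extracted amplicon the **inner** (primer-
trimmed) length decides the representation:

* inner length `< merge_threshold - near_window` (i.e. < 490): the two
  reads overlap comfortably and are emitted **merged**;
* inner length `> merge_threshold + near_window` (i.e. > 510): overlap is
  impossible or unreliable, reads stay **paired**;
* within the window: **both** representations are emitted, since merge
  success near the boundary depends on run-specific quality.

The forward read is the first `read_len` bases of the inner sequence; the
reverse read is the reverse complement of the last `read_len` bases.

# Consensus of paired-read annotations

Annotations are ranked lineages (domain … species, 7 ranks) in which the
species slot may hold a *candidate set* (e.g. `crispatus/gasseri/jensenii`).
The consensus of a forward and a reverse annotation applies three rules:

1. **Conflict → truncate.** At the first rank where both are filled and
   disagree, the consensus is cut to the last agreeing rank (an LCA).
2. **One-sided → keep.** Where only one annotation is filled, its value is
   kept: a prefix-compatible, more detailed annotation survives intact.
3. **Species → intersect.** Species evidence is the candidate set (a
   definite species is a singleton set). The consensus species is the
   intersection; a singleton intersection becomes a definite species, and an
   **empty intersection falls back to genus level** rather than inventing a
   compromise.

The operation is commutative and idempotent, which the test suite
property-checks on 10,000 random annotation pairs. Note that depth can
legitimately *increase* past either input's nominal depth when two
ambiguous candidate sets intersect to a singleton.

# Quality control for the concatenation path

When reads are concatenated instead of merged, per-read quality control is:

1. **3′ quality truncation** at `q_cutoff = 15`: walking from the 3′ end,
   cut where the partial sum of `(q_cutoff − Q)` is maximal and positive.
   Ties are broken toward trimming **more**, the conservative choice for a
   quality filter. If no partial sum is positive the read is untouched.
2. **Length gate**: a read trimmed below `trim_len = 270` is rejected
   (`rejected_short`); survivors are cut to exactly 270 so that every kept
   concatenated pair has identical length 540. 270 is chosen so that 2 ×
   270 spans the target amplicon while leaving headroom below typical
   300-cycle read lengths.
3. **Expected-error gate** over the concatenated 540 bases: $EE = \sum_i
   10^{-Q_i/10}$; pairs with `EE > 4` are rejected (`rejected_ee`). An EE
   budget, unlike an average-quality cutoff, penalizes a few terrible bases
   the way the error process actually behaves.

```{r ee}
expected_errors(rep(30L, 540))  # uniform Q30 passes comfortably
expected_errors(rep(15L, 540))  # uniform Q15 fails the EE <= 4 gate
```

# Triaxial profile comparison

Three-taxon profiles (by default *L. crispatus*, *L. iners*,
*G. vaginalis*) are normalized onto the 2-simplex and compared by Manhattan
(L1) distance. On the simplex the maximum attainable L1 distance between
two profiles is **2** (attained by opposite vertices), not 3: the package
documents and asserts the ≤ 2 bound. Distance 0 occurs exactly for
identical profiles.

```{r triax}
a <- normalize_three_taxa(c("Lactobacillus crispatus" = 1,
                            "Lactobacillus iners" = 0,
                            "Gardnerella vaginalis" = 0))
b <- normalize_three_taxa(c("Lactobacillus crispatus" = 0,
                            "Lactobacillus iners" = 1,
                            "Gardnerella vaginalis" = 0))
manhattan_distance(a, b)
```

# The synthetic-fixture generator

`make_reference_db()` is the package's study-conditions generator, not a
tuning dial. Given a `fixture_spec()` it emulates the relevant structure of
a curated 16S database:

* background sequences are rejection-sampled to be free of incidental
  primer sites, so planted truth is exact;
* each record is planted, per its assigned category, with a concrete
  variant of the forward and/or reverse primer at recorded coordinates
  (`both`, `fwd_only`, `rev_only`, `none`);
* a chosen fraction is flagged 5′-truncated (necessarily among the
  reverse-only records, mirroring how truncation manifests);
* category counts come from half-up rounding of the requested fractions,
  and every assembled record is re-verified by `find_sites()` before being
  accepted.

What it does **not** emulate: chimeras, sequencing error inside the primer
site, length heterogeneity beyond the configured ranges, or realistic
taxonomic abundance distributions — none of which the exact-match model
consumes. `make_fastq_pairs()` similarly engineers read pairs whose QC fate
is provable by construction (uniform Q38 passes; a Q2 tail forces
`rejected_short`; uniform Q16 evades trimming but fails the EE gate).

Determinism: generation runs inside a private RNG stream
(`with_fixture_seed()`), so the same spec yields byte-identical output and
the caller's `.Random.seed` is restored afterwards.

# Numerical conventions

* Half-up rounding (`floor(x * 10^d + 0.5) / 10^d`) for reported counts and
  percentages, avoiding banker's-rounding surprises in tables.
* 0-based half-open coordinates everywhere; inner span excludes both primer
  sites.
* Quality scores are integer Phred values in `[0, 93]`, serialized
  Phred+33.
* Test problem sizes (databases of 10–1,000 records over ≥ 5 seeds; 10,000
  consensus pairs; full simplex grids) are the package's own choice of
  desk-scale sizes: large enough for the combinatorics to exercise every
  branch, small enough that the whole suite runs in about a minute on one
  CPU.
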