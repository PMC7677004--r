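Package: ampliscreen
Title: In Silico Evaluation of 16S rRNA Primer Sets for Vaginal Microbiome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing degenerate 16S rRNA primer pairs and
    amplicon-processing choices against a taxonomically annotated reference
    database, with a focus on the human vaginal microbiome. Implements exact
    full-length degenerate-primer site search, per-record in-silico PCR with
    pessimistic and optimistic handling of 5'-truncated reference records,
    read simulation with merge-versus-paired rules, a lowest-common-ancestor
    consensus scheme for paired-read taxonomic annotations, expected-error
    based quality filtering for concatenated read pairs, triaxial (three-taxon)
    profile normalization with Manhattan-distance comparison against qPCR, and
    a deterministic synthetic-fixture generator with planted primer sites.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
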