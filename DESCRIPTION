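Package: duprec
Title: Duplicon Insertion Breakpoint Detection and Template-Driven
    Sequence Reconstruction from Paired-End Reads
Version: 0.1.0
Authors@R:
    person("Duprec", "Maintainers", email = "duprec@example.org",
           role = c("aut", "cre"))
Description: Given paired-end mappings against a reference genome and a set
    of candidate copy-number-gain regions, locates the insertion
    breakpoints of extra, non-tandem duplicon copies by clustering the
    external ends of discordant one-end read pairs and scoring each
    cluster for mapping specificity and orientation composition.  At every
    accepted breakpoint the inserted sequence (and every homologous copy)
    is reconstructed by template-driven assembly: a profile hidden Markov
    model is seeded from the reference template, trained boundary-in from
    anchored reads with error-rate-constrained emission updates, and
    two-end reads are recruited iteratively by anchored Viterbi decoding
    until convergence.  A self-contained simulator (reference genomes with
    repeat families, donor genomes with planted diverged duplicons,
    paired-end reads, and a seed-and-extend mapper) plus an evaluation
    module make the whole accuracy experiment reproducible offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
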