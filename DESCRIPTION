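Package: mirflow
Title: Small RNA Sequencing Analysis of Differential miRNA Expression
Version: 0.1.0
Authors@R:
    person("mirflow", "developers", email = "mirflow@example.org",
           role = c("aut", "cre"))
Description: An end-to-end small RNA-seq analysis pipeline for comparing
    miRNA expression between two insect strains: adapter trimming and
    read accounting, tag collapsing, annotation against non-coding RNA
    and miRNA references, novel miRNA discovery by hairpin folding with
    a nearest-neighbor stacking energy model, count-based differential
    expression using an Audic-Claverie style exact test, miRNA
    target-site prediction with complementarity penalties and duplex
    hybridization energy, hypergeometric GO/KEGG enrichment, and qPCR
    validation arithmetic.  Includes a synthetic-data generator that
    produces complete corpora (references, annotation maps, FASTQ
    libraries) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
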