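Package: antmine
Title: Genome-Mining of Defense Peptides and Neuropeptide Precursors in Ant Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible genome-mining pipeline for discovering
    peptide-encoding genes (defensins, abaecins, pilosulins, inotocins,
    allatostatins and related neuropeptide hormones) in whole-genome
    shotgun contigs. Implements six-frame translated homology search with
    exact Smith-Waterman local alignment under BLOSUM62, GeneWise-style
    spliced protein-to-genome alignment with a canonical GT-AG intron
    model, homology-transfer annotation of precursor proteins into
    signal, pro- and mature-peptide segments with dibasic-cleavage and
    glycine-amidation motif detection, antimicrobial-peptide feature
    profiling (formal net charge, cysteine network and CSab motif,
    composition), progressive multiple alignment with sequence-logo
    information content, and a synthetic-genome simulator that plants
    precursor genes of known architecture for ground-truth benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
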