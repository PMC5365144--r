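Package: editome
Title: Detection and Adaptive-Evolution Analysis of A-to-I RNA Editomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical toolkit for characterising adenosine-to-inosine (A-to-I)
    RNA editing from multi-library RNA-seq allele counts. Implements a binomial
    sequencing-error model with joint cross-library editing probabilities and
    Benjamini-Hochberg FDR control, five-class site confidence tiers, the
    nonsynonymous/synonymous (N/S) selection test with adaptive-fraction (alpha)
    estimation and bootstrap confidence intervals, read-resampling simulations
    of detection bias, confident-absence probabilities for conservation and
    polymorphism calls across strains and species, position-probability-matrix
    motif scoring of editing-site contexts, density/association analyses, and a
    fully seeded synthetic-data generator that emulates the assumed statistical
    structure end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
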