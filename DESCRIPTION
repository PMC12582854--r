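Package: ayemaps
Title: Fine-Scale Mutation and Recombination Rate Maps from Divergence and
    Linkage Disequilibrium
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds fine-scale genomic rate maps for the aye-aye (Daubentonia
    madagascariensis) analysis workflow: windowed neutral divergence and
    nucleotide diversity tracks with accessibility masking, conversion between
    divergence, mutation rate and divergence time, linkage-disequilibrium-based
    recombination rate estimation by pairwise composite likelihood over a
    demography-aware Monte-Carlo two-locus lookup table (with outlier filtering
    and rescaling to a pedigree-based genetic map length), a coalescent
    simulation benchmark of the estimator under population decline, and a Haar
    wavelet multi-scale correlation analysis of recombination against
    diversity, divergence, GC-content and exon-content. A seeded synthetic-data
    generator (substitutions, SMC' haplotype panels, annotations, motif
    placements) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    IRanges,
    GenomicRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
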