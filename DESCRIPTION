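Package: genloss
Title: Gene-Loss and Pseudogenization Inference from Genome Assemblies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers the coding status of genes across related genomes. Maps
    reference exon models onto target genomic sequences with a seeded
    semi-global affine-gap aligner, calls open-reading-frame disrupting
    mutations (premature stop codons, frameshift and in-frame indels,
    start-codon loss, non-canonical splice sites and exon deletions), groups
    equivalent mutations across species and places shared mutations on a
    rooted species tree under Dollo parsimony, validates candidate mutations
    against raw sequencing reads, and assesses locus presence or absence via
    flanking-gene synteny and assembly-gap scanning. Includes a fully seeded
    simulator that evolves gene loci on a species tree with branch-planted
    mutations, assembly gaps and read sets, plus ready-made scenarios that
    reproduce the published mutation maps of the cetacean melatonin pathway
    genes Aanat, Asmt, Mtnr1a and Mtnr1b.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
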