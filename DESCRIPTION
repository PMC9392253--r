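Package: mitostructkit
Title: Structural Variation Analysis of Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing structural variation in circular plant
    mitochondrial genomes: detection and length-classification of dispersed
    repeats by self-comparison, identification of plastid-derived segments,
    phylogenetic generalized least squares correlation of repeat content with
    genome size, estimation of repeat-mediated homologous recombination
    frequency from long sequencing reads, exact signed inversion distances
    between circular synteny block orders with rearrangement rates on dated
    phylogenies, sliding-window nucleotide diversity and Weir-Cockerham FST
    scans for selective sweeps, and read-depth-ratio genotyping of large
    deletions. A synthetic-data module generates every input class with known
    ground truth so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    vcfR
Config/testthat/edition: 3
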