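Package: metamark
Title: Marker-Gene Taxonomic, Strain-Level and Functional Profiling of
    Shotgun Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative profiling of shotgun metagenomic
    communities from species-specific marker genes. Builds species
    pangenomes from annotated genomes, computes coreness and uniqueness
    statistics for gene families, and selects tiered clade-specific
    marker genes. Estimates per-clade relative abundances by
    quantile-trimmed robust averaging of marker coverages with an
    estimate of the unknown community fraction, reconstructs per-sample
    consensus marker genotypes for strain-level phylogenetics and
    transmission inference, types strains by pangenome gene-family
    presence/absence from coverage curves, and performs tiered
    functional profiling with coverage, identity and top-score filters.
    A fully deterministic synthetic-community simulator provides
    genomes, strains, reads and gold-standard profiles so that every
    component can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    tools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
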