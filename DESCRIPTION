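Package: bdellocomp
Title: Comparative Genomics of Predatory Bdellovibrionota
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative genomics of the predatory bacterial
    phylum Bdellovibrionota: quality filtering of genomes and
    metagenome-assembled genomes, k-mer based average nucleotide identity
    (ANI) estimation and dereplication, classification of 16S rRNA
    metagenomic Illumina tags (miTags) against a labelled reference set
    with depth-stratified relative abundance profiling, presence/absence
    and copy-number analytics over KEGG/COG/MEROPS/CAZy annotations
    (group-specific gene calling, marine-enrichment tables, peptidase
    Venn partitions, CAZy class profiles), and wildcard protein motif
    scanning for the chitinase catalytic motif. A synthetic-data module
    provides seeded simulators and deterministic worked-example fixtures
    so every stage runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    yaml,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
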