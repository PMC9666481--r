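Package: mitocomp
Title: Mitogenome Composition, Architecture, Codon Usage and
    Distance-Based Phylogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterization of annotated animal mitochondrial genomes,
    built around the analyses routinely reported for newly sequenced tick
    (Ixodida) mitogenomes: per-region nucleotide composition with AT/GC
    strand-asymmetry skews, gene-architecture bookkeeping (junction
    overlaps and intergenic spacers on the circular molecule, strand and
    feature-class censuses), protein-coding gene extraction with
    incomplete stop-codon completion, relative synonymous codon usage
    (RSCU) and amino-acid frequencies under the invertebrate
    mitochondrial code, and distance-based Minimum Evolution phylogenetics
    (neighbor-joining start, ordinary least-squares branch lengths,
    nearest-neighbor-interchange search, nonparametric bootstrap support)
    over concatenated protein-coding gene alignments. A seeded synthetic
    mitogenome generator with the 37-gene tick gene order, and a
    sequence evolver along a tree, make the whole pipeline testable
    without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
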