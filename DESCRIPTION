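Package: ytrace
Title: Tracing Y Chromosome Dissolution by Rearrangement Parsimony,
    Segmental Duplication Detection, and Strata Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational toolkit for reconstructing how a mammalian Y
    chromosome dissolves into the X chromosome and autosomes, motivated by
    the Y-less spiny rats (genus Tokudaia). Provides a signed-inversion
    rearrangement core (Hannenhalli-Pevzner distance with an exhaustive
    breadth-first oracle), maximum-parsimony enumeration of ancestral
    insertion configurations for a Y-derived synteny-block insertion,
    fusion-only ancestral karyotype reconstruction from windowed
    whole-chromosome alignments, iterative detection of boundary-associated
    segmental duplications (BASDs) with flank-provenance labelling and
    circular-intermediate (eccDNA) inference, pseudoautosomal/stratum
    boundary detection from heterozygous-SNP density, repeat-unit tiling
    and palindrome annotation, and Y-linked gene intact/pseudogene
    classification. A synthetic-genome generator with ground-truth tables
    supports end-to-end recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
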