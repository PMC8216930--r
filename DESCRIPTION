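Package: mitoarch
Title: Comparative Mitogenome Architecture, Composition and Supermatrix Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated circular
    mitochondrial genomes, with defaults tuned to the 37-gene lepidopteran
    gene order. Recomputes gene-architecture tables (sizes, intergenic
    nucleotides, overlaps and spacers, strand assignment, start/stop codon
    classification including incomplete T/TA stops), region-wise nucleotide
    composition with AT- and GC-skew, relative synonymous codon usage under
    the invertebrate mitochondrial genetic code, A+T-rich control-region
    poly-T/poly-A run detection, and concatenated phylogenetic supermatrices
    (all codon positions, with RNA genes, or with third positions removed)
    together with partition definitions. Includes readers and writers for
    GenBank flatfiles, FASTA, NCBI 5-column feature tables, relaxed PHYLIP
    and NEXUS matrices, and a seeded synthetic-mitogenome generator for
    fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
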