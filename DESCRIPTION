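Package: AluEdit
Title: Structural, Sequence and Thermodynamic Analysis of A-to-I RNA Editing
    in Alu Repeats
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising adenosine-to-inosine (A-to-I) RNA
    editing within Alu inverted repeats. Calls putative editing sites from
    RNA-to-genome alignment mismatches (SNP removal, Alu intersection,
    mismatch clustering), builds the double-stranded RNA genomic
    neighborhoods formed by sense/antisense Alu pairs, classifies every
    nucleotide of a predicted secondary structure into helix, interior
    loop, bulge, hairpin, multibranch junction or exterior strand,
    derives per-site structural and sequence context (closest-edge
    position, opposite nucleotide, flanking bases), computes stratified
    editing-frequency, enrichment-factor and contingency statistics, and
    performs Boltzmann-ensemble calculations over suboptimal folds
    (per-site substructure probabilities and structural entropy). A
    seeded synthetic-data generator with a known multiplicative editing
    model makes the whole pipeline testable end to end without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
biocViews: Sequencing, Transcriptomics, RNASeq, StructuralPrediction,
    Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
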