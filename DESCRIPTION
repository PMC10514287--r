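Package: gappedmotifs
Title: Gapped Amino-Acid Motif Analysis of Targeting Peptides and
    Antimicrobial Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Enumeration, matching and statistical characterization of short
    gapped (discontinuous) amino-acid motifs in N-terminal targeting peptides
    (chloroplast and mitochondrial transit peptides, signal peptides) and
    antimicrobial peptides. Provides dataset filtering with per-step removal
    ledgers, lazy gapped k-mer counting into sparse motif-by-sequence
    matrices, presence-frequency and within-sequence repeat statistics,
    positional start-density profiles on a length-scaled axis with rule-based
    region classification, reduced physicochemical alphabets (7, 8 and 10
    groups), taxon comparisons by Mann-Whitney U tests with
    Benjamini-Hochberg correction, and a synthetic peptide generator with
    planted-motif ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    data.table,
    jsonlite,
    methods,
    stats,
    tibble,
    tools,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
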