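Package: ngpd
Title: Next-Generation Phage Display Enrichment Analysis and One-Site ITC Fitting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for next-generation phage display (NGPD) experiments in
    which biopanning output is read out by deep sequencing of the
    insert-coding region. Includes a synthetic-data generator for barcoded
    amplicon read sets with known ground truth, FASTQ demultiplexing,
    three-frame translation and flank-anchored peptide extraction,
    enrichment ranking of peptides by the two-proportion Z statistic
    (target versus control selections), ZOOPS expectation-maximisation
    motif discovery with degenerate consensus-pattern matching, and
    weighted nonlinear least-squares fitting of one-site isothermal
    titration calorimetry (ITC) binding isotherms with synthetic
    thermogram simulation for parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    minpack.lm,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
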