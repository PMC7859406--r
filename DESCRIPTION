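Package: kinetoedit
Title: Reconstruction and Quantification of Kinetoplastid U-Indel RNA Editing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for characterizing prokinetoplastid genomes and
    mitochondrial transcriptomes: thymidine-depleted homology search for
    cryptogenes of pan-edited mRNAs, constrained dynamic-programming
    reconstruction of uridine insertion/deletion RNA editing with deaminative
    (C-to-U, A-to-I) edit detection, guide-RNA/minicircle architecture
    analysis with G:U wobble-aware duplex scoring, spliced-leader
    trans-splicing detection, degenerate stem-loop motif search for the 9S and
    12S mitochondrial rRNAs, prey-decontamination filtering, gene
    polarity/clustering statistics, and a seeded synthetic-data generator with
    ground truth for end-to-end parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
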