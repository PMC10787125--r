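Package: circleave
Title: Degradome-Based Detection of miRNA-Mediated Circular RNA Cleavage
Version: 0.1.0
Authors@R:
    person("circleave", "developers", email = "circleave@example.org",
           role = c("aut", "cre"))
Description: Toolkit for analysing the decay and internal structure of plant
    circular RNAs (circRNAs). Implements weighted 5'-end degradome pileups,
    sliding-window cleavage-peak calling with binomial significance,
    miRNA slice-site prediction via a duplex minimum-free-energy model with
    MFE-ratio filtering, back-splice-junction-spanning decay-read detection,
    rolling-circle open reading frame prediction with unique-peptide support
    filtering, circRNA typing and alternative back-splicing classification,
    RPM quantification and differential expression, and a permutation
    framework testing feature enrichment in circRNA transcribed regions.
    A deterministic synthetic-data generator plants ground-truth cleavage
    sites, circles, ORFs and enriched features so that every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
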