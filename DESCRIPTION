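Package: dpcseq
Title: Simulation and Analysis of Genome-Wide DNA-Protein Crosslink Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing genome-wide maps of DNA-protein crosslinks
    (DPCs) obtained by crosslink-enrichment sequencing, together with a seeded
    synthetic-data generator that emulates formaldehyde-induced DPC formation
    and transcription-coupled removal in repair-proficient and repair-deficient
    genotypes. Implements chromatin-state fold enrichment of DPC peak lists,
    CPM-normalised binned coverage tracks, expression-stratified TSS
    metaprofiles with position-wise genotype comparison, relative removal
    efficiency (RRE) at repetitive loci via a reconstructed reference with
    hard-trimmed mismatch-free read counting, and delta-Ct qPCR percent-removal
    statistics with paired one-tailed t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
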