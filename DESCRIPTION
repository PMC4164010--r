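Package: archori
Title: Prediction of Replication Origins in Archaeal Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts replication origins (oriCs) on circular archaeal
    chromosomes from annotated genome sequences. Combines Z-curve base
    composition disparity analysis (AT, GC, RY and MK disparity curves with
    extremum location and rotation to the GC-disparity maximum), scanning of
    intergenic regions for origin recognition box (ORB) motifs with
    position-specific scoring matrices and exact dynamic-programming
    p-values, classification of gene products into replication-related roles
    (Orc1/Cdc6, Whip, primase), and annotation of exact direct and
    palindromic repeats. Candidate intergenic regions flanked by
    replication-related genes and containing ORB hits, or containing three
    or more ORB hits, are reported as predicted origins with a full evidence
    bundle. Includes a seeded synthetic genome generator with planted
    origins for validation, an evaluation harness computing sensitivity and
    precision against reference origin sets, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
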