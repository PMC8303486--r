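Package: orthosplice
Title: Custom Proteogenomic Databases and Cross-Species Mapping of
    Alternatively Spliced Proteoforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds customized protein sequence databases that contain
    tryptic peptides exclusive to noncanonical alternatively spliced
    proteoforms, after removing transcripts that are candidate targets of
    nonsense-mediated decay. Maps orthologous proteoforms between two
    species through identical proteotypic peptides using NCBI gene
    orthology and UniProt identifier mapping tables, and quantifies
    differential peptide abundance from isobaric-label (iTRAQ) reporter
    intensities with a paired log2-ratio one-sample t-test. Includes
    transcripts-per-million and 2^-ddCt expression statistics, a seeded
    synthetic-fixture generator with ground truth for end-to-end testing,
    and a command-line pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
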