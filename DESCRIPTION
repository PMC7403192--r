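Package: repclone
Title: Single-Cell B Cell Receptor Repertoire Annotation and Convergent
    Clone Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of paired heavy/light chain B cell receptor (BCR)
    repertoires from single cells, as used to characterise cerebrospinal
    fluid B cells in autoimmune encephalitis. Provides native V(D)J
    segment assignment by local alignment against a germline reference,
    junction/CDR3 extraction from conserved anchors, productivity
    classification and somatic hypermutation counting; cell completeness
    classification, clonal clustering by V/J gene and junction amino acid
    identity, detection of convergent clones and shared paired-chain
    clonotypes across patients, and cross-cohort CDR3 search; repertoire
    statistics (gene family usage, V-J combinations, CDR3 length
    distributions, mutation rates) with the normality-gated test
    selection common in the field; and a V(D)J recombination simulator
    with known ground truth for end-to-end validation. Reads and writes
    AIRR Rearrangement TSV and MiXCR-style clone tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
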