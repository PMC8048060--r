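Package: barcodeGap
Title: Barcoding-Gap Analysis, Mislabel Detection and Diagnostic
    Fragments for Fungal ITS Alignments
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for curating reference sets of fungal internal
    transcribed spacer (ITS) barcode sequences. Computes pairwise
    p-distances with pairwise deletion of gaps and ambiguous sites and
    site-bootstrap standard errors; summarises within- and between-species
    distance ranges and estimates a barcoding-gap cut-off; flags
    mislabeled database records by distance to designated reliable
    reference sequences with a genus-membership gate; and discovers
    species-diagnostic alignment fragments suitable as hyperbranched
    rolling circle amplification (HRCA) probe candidates, reporting IUPAC
    consensus sequences with 1-based alignment coordinates. A seeded
    synthetic-data generator produces species-structured alignments with
    known divergences, indel blocks, planted diagnostic fragments and
    injected mislabels so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
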