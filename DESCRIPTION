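Package: orfdisplay
Title: Reading-Frame Analysis and Simulation for ORFeome Phage Display Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Informatics for functional metaproteome (ORFeome) phage display:
    classify sequenced phagemid inserts by reading-frame fate relative to the
    pIII fusion frame (in-frame, stop-interrupted, rescued by an alternative
    start codon), trim vector flanks with frame-integrity checks, filter reads
    by expected error rate, compute library diversity statistics
    (dereplication, redundancy, replicate overlap, Shannon effective counts),
    simulate library construction, ORF enrichment, sequencing and biopanning
    with known ground truth, and analyse two-cohort serology ELISA tables with
    background subtraction and Mann-Whitney tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
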