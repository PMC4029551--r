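Package: omconnect
Title: Optical-Map-Assisted Contig Connection and Gap Closure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Connects neighbouring genome-assembly contigs that have been
    ordered on a restriction optical map. Contigs are placed on the map by
    restriction-fragment alignment (or by importing an external placement
    table), the map is rescaled against contig-side fragment lengths, the
    bidirected contig graph is searched with a modified depth-first search
    that records repeat loops instead of re-traversing them, and each
    inter-contig gap is closed with the candidate contig path whose length
    best matches the rescaled gap size. Includes a synthetic-data generator
    with known ground truth (repeat structure, map scale and sizing noise)
    for end-to-end validation, plus readers and writers for contig FASTA,
    Newbler 454ContigGraph.txt, a generic edge-list graph dialect, and a
    plain-text optical-map format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
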