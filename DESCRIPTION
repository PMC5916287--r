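Package: mitocirc
Title: Circularity Inference for De Novo Assembled Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tests whether a de novo assembled scaffold represents a closed
    circular molecule (typically a mitochondrial genome). Duplicated k-mers
    separated by a minimum span delimit a putative circular sequence, which
    is rotated ("flipped") so its original ends meet mid-sequence; the
    original short reads are then re-mapped end-to-end against the flipped
    candidate and circularity is judged from the average alignment score
    and a per-position "connectivity" statistic counting reads that support
    each base's adjacency to both neighbours. A permutation study perturbs
    the candidate's ends with random insertions or deletions to quantify the
    sensitivity and false-positive behaviour of the verdict. Includes a
    self-contained read simulator for circular genomes and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rsamtools,
    S4Vectors,
    Rcpp,
    jsonlite,
    optparse,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
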