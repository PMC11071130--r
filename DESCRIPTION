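Package: cdbgzip
Title: Lossless Disk Compression of Colored de Bruijn Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Compresses a colored de Bruijn graph (a collection of k-mer sets
    sharing many k-mers) to a compact binary archive and restores it exactly.
    The union k-mer set is laid out as a spectrum-preserving string set
    (simplitigs), which fixes a global k-mer order; the per-k-mer color
    vectors are then compressed with Huffman-coded color-class identifiers,
    a delta-encoded class table, optional per-simplitig local class tables,
    and a per-simplitig bit grammar with run-length and small-difference
    encodings chosen by an exhaustive per-simplitig mode search. Includes a
    synthetic colored-graph generator for end-to-end testing and a small
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
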