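Package: properalign
Title: Global Protein-Protein Interaction Network Alignment by Percolation Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-stage global alignment of pairs of protein-protein interaction
    (PPI) networks. Stage one greedily matches protein couples with high BLAST
    bit-score sequence similarity (above a threshold ell) into a seed set;
    stage two expands the alignment by percolation graph matching, repeatedly
    matching the unmatched couple with the most already-matched common
    neighbours (at least r of them). Includes the standard topological and
    functional alignment quality measures (node correctness, conserved
    interactions, EC, ICS, S3, LCSC, GO consistency, average normalized
    bit-score), pathway-level conservation measures with a
    conserved-interaction threshold, a correlated random-bigraph simulator for
    benchmarking with known ground truth, readers and writers for edge-list,
    BLAST tabular, GAF and pathway-membership files, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
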