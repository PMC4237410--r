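Package: tccn
Title: Community Detection in Topology-Constrained Correlation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds significance-filtered correlation networks that are
    optionally constrained by a physical or geographic contact topology
    (grid neighbours, adjacent states, inter-residue contacts), detects
    community structure by fast-greedy modularity optimization, and
    corrects the over-fragmentation that topology constraints induce with
    a linear-discriminant confidence-ellipse collision filter followed by
    a permutation test of module bipartitions. Includes a Cholesky-based
    structured simulator with known ground truth, a pair-counting F-score
    benchmark, and readers for semicolon-delimited geometric-morphometric
    coordinate files and US Senate roll-call vote tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
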