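Package: odtnet
Title: Optimal Displayed Trees of Phylogenetic Networks Under Deep
    Coalescence and Duplication
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Embeds rooted binary gene trees (including MUL-trees) into
    rooted binary phylogenetic networks. Provides an O(|G||N|) dynamic
    program for the optimal deep-coalescence and duplication scenario
    scores with used-reticulation-edge backtracking, exact
    optimal-displayed-tree solvers by conflict resolution for tree-child,
    relaxed and level-k networks, branch-and-bound cost bounds, a naive
    enumeration baseline, exhaustive small-scale oracles (network
    unfolding, scenario enumeration, a cubic dynamic program), extended
    Newick input/output, and simulators for random tree-child/relaxed
    networks and Yule-Harding gene trees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
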