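Package: ndtree
Title: Node-List Phylogenetic Trees with Local Updates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Represents rooted phylogenetic trees as a dictionary of named
    node records, each carrying its ancestor path, immediate children,
    descendant tips and precomputed branch-length summaries. Because every
    node stores its local context, tips can be added or removed by touching
    only the insertion path and the subtree below it rather than rebuilding
    the whole tree, and per-node statistics vectorise over the node list.
    Provides Fair Proportion evolutionary distinctness, Faith phylogenetic
    diversity, patristic distance matrices, UniFrac-style community overlap
    with a permutation test for phylogenetic turnover, taxonomically
    constrained tip pinning, an evolutionary-distinctness-biased Markov
    tree-growth simulator, Newick input/output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), ape, phangorn, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
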