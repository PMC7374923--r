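Package: chaincover
Title: Chain Subgraph Covers and the Quantitative Lock/Key Model of
    Cytoplasmic Incompatibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Algorithms for analysing cytoplasmic incompatibility (CI)
    data under the quantitative Lock/Key model. Incompatible crosses
    between males and females are recorded as edges of a bipartite
    graph; explaining the data with k toxin/antitoxin (Lock/Key)
    molecule pairs is equivalent to covering the edges with k chain
    subgraphs (bipartite graphs with no induced 2K2). The package
    enumerates all maximal chain subgraphs with polynomial delay,
    computes the exact minimum chain-cover size by inclusion-exclusion
    with exact big-integer arithmetic, enumerates all minimal chain
    covers through essential-edge reduction to minimal hypergraph set
    covers, constructs Lock/Key quantity matrices that explain an
    incompatibility matrix, and exposes the interval-order view of the
    same problems (interval dimension of bipartite posets, minimal
    interval extensions and maximal interval reductions). Brute-force
    oracles, synthetic generators (antimatching graphs, random
    bipartite graphs, planted covers) and a command-line front-end are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
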