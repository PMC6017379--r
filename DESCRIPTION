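Package: pathphylo
Title: Phylogenetic Reconstruction from Multiple Metabolic Pathway Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns the common metabolic pathways of a set of organisms by
    building union graphs of one-to-one reaction mappings (greedy
    maximum-weight bipartite matching on enzyme and compound similarity),
    detects mapped functional modules by affinity propagation clustering of
    composite nodes, scores inter-organism similarity from the largest common
    connected sub-graphs of the largest mapped modules, and reconstructs a
    distance-based phylogenetic tree from the resulting matrix. Includes
    readers for a native pathway exchange format and a minimal KGML subset,
    a seeded synthetic organism-set generator with known generating tree,
    pathway perturbation utilities, and a cousin-pair tree similarity
    measure for comparing reconstructed topologies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
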