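Package: metapath
Title: Metabolic Pathfinding by Conserved Atomic-Group Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds ranked metabolic pathways between two compounds by tracking
    conserved atomic groups through an atom-mapped reaction network. Reaction
    edges are weighted by a blend of reaction Gibbs free energy and
    reactant-product structural similarity, candidate routes are extracted as
    loop-free k-shortest paths on the resulting atomic-group transfer graph,
    and computed pathways can be scored against reference pathways with
    order-respecting inclusion metrics (sensitivity, positive predictive
    value, accuracy, F-measure). Includes a synthetic atom-mapped network
    generator with planted pathways and currency-metabolite decoys, readers
    and writers for an open JSON/TSV network dialect, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    readr,
    rlang,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
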