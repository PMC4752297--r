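Package: pdnet
Title: Binary-Relation Network Analysis of CellDesigner Disease Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts SBGN process-description pathway maps (SBML Level 2
    with the CellDesigner annotation dialect) into binary-relation graphs by
    decomposing each reaction into reactant-product and modifier-product
    pairs, computes exact node and edge betweenness centrality with the
    Brandes algorithm, extracts the top-k high-edge-betweenness "primary
    pathway" and k-hop neighbourhoods around named seed molecules, and
    generates synthetic CellDesigner-dialect maps with planted hubs for
    ground-truth validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    xml2,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
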