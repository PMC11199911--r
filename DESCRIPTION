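Package: treekit
Title: Reading, Writing and Manipulating Phylogenetic Trees and Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A standalone utility library for phylogenetic trees and networks:
    a stack-based Newick parser that scales to millions of tips, readers for
    Newick, Nexus, PhyloXML, NeXML and PhyJSON (including BEAST and NHX branch
    annotations, multifurcations and extended-Newick hybrid nodes), iterative
    Newick/Nexus writers with pluggable annotation dialects, tree manipulation
    (rerooting, ladderisation, clade extraction, most recent common ancestors,
    pruning and grafting), tree statistics (tree length, Sackin and Colless
    imbalance, the Pybus-Harvey gamma statistic, internal-to-external branch
    length ratio, root-to-tip regression), a seeded synthetic-tree simulator,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
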