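Package: compeff
Title: Compartment-Resolved Efficiency Analysis of Protein Interaction Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates the efficiency of signaling pathways from the observed
    frequency of intra- and inter-compartmental protein-protein interactions.
    Builds a symmetric compartment-by-compartment interaction-frequency matrix
    from an interactome and a subcellular localization catalog, scores pathway
    reactions by looking up the matrix entries of their participants, compares
    pathway collections against permutation null models (independent protein
    replacement per reaction and consistent replacement per pathway), and
    clusters pathways by the correlation distance between their
    reaction-efficiency distributions. Includes a synthetic-data generator for
    compartmentalized interactomes and pathway collections with known ground
    truth, readers and writers for localization tables, edge lists, a
    PSI-MITAB 2.5 subset, KGML pathway files, reaction-list tables and Newick
    dendrograms, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    mclust,
    optparse,
    yaml
Config/testthat/edition: 3
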