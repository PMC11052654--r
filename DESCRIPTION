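Package: cytosom
Title: Self-Organizing-Map Clustering and Metaclustering for Cytometry Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-level clustering of flow and mass cytometry data: events are
    over-clustered onto a self-organizing map (SOM) grid, the node codes are
    joined by a minimum spanning tree for visualization, and consensus
    hierarchical clustering merges nodes into metaclusters that typically
    correspond to cell types. Includes an FCS 3.0/3.1 reader and writer,
    arcsinh and z-score preprocessing, star and pie plots of the clustered
    model, matched-F1 and purity evaluation against reference cell labels, a
    synthetic cytometry-sample generator, an HDF5 two-modality (cell, cluster)
    result container, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    xml2
SystemRequirements: HDF5 (libhdf5)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
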