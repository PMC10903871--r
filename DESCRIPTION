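Package: pbcseg
Title: Persistence-Based Clustering Segmentation of Cells in 3D Microscopy Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Instance segmentation of ramified cells (e.g. microglia) in
    multi-channel 3D fluorescence z-stacks by zero-dimensional persistence-based
    clustering of the intensity superlevel-set filtration (ToMATo-style
    mode seeking with a prominence threshold), followed by nucleus-driven
    refinement to a one-to-one cell/nucleus correspondence, cluster-level mask
    editing with replayable sessions, and voxel-wise evaluation (Dice/F1,
    Jaccard, false positive and false negative percentages) against ground
    truth. Includes a synthetic scene generator for branched cells with nuclei,
    blur and noise, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    ggplot2,
    optparse,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
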