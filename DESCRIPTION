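Package: cellcountr
Title: Cell Counting on Microscope Images with Redundant Count Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Counts cells on phase-contrast microscope images with a fully
    convolutional network that regresses redundant count maps: every output
    pixel reports how many annotated cells fall inside its receptive field,
    so each cell is counted once per covering pixel and the total count is
    the map sum divided by the kernel area. The package builds count-map
    targets from one-pixel cell annotations, trains a Count-Ception-style
    inception network written from scratch (Glorot initialisation, spatial
    batch normalisation, Adam, L1 loss), tiles large frames into quadrants
    with zero padding, counts red-fluorescent cells by red-channel
    thresholding, and provides the downstream evaluation metrics and
    rank-based time-course statistics. A seeded generator of synthetic
    phase-contrast-like scenes with ground-truth annotations supports
    testing end to end, and a JSON-RPC 2.0 handler plus command-line
    interface expose counting to scripts and services.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
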