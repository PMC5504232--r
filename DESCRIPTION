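Package: geodca
Title: Distance-to-Connected-Areas Gradients on Cortical Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Surface-based analysis of connectivity distance gradients.
    Computes, for every vertex of a triangular cortical mesh, the mean
    geodesic distance to its most strongly functionally connected vertices
    ("distance-to-connected-areas"), tests whether this map increases with
    geodesic distance from primary-cortex landmarks against a
    random-network-topography permutation null, and groups functional
    networks by the Jensen-Shannon divergence between their distance
    distributions.  Includes geodesic distance approximation on triangle
    meshes, per-hemisphere functional-connectivity construction with
    node-wise top-percentile thresholding, size-matched random patch
    layouts with a binary within-network connectivity model, test-retest
    ICC maps, and a synthetic-cortex generator (icosphere meshes, tiered
    parcellations with primary anchors, distance-decaying Gaussian time
    series) with known ground truth for recovery studies.  Readers and
    writers for FreeSurfer surface/curv/annot, GIFTI, OFF and plain-text
    formats are provided.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
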