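Package: redlisting
Title: Species Red-Listing Tools: Range Metrics, Distribution Mapping
    and the Red List Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spatial and statistical tools to support species extinction-risk
    assessments under the IUCN criteria. Computes Extent of Occurrence
    (minimum convex polygon) and Area of Occupancy (2 km grid) from
    occurrence records or predicted ranges, cleans occurrence data
    (snapping to valid cells, environmental-space outlier detection,
    spatial thinning), maps ranges from occupied habitat patches or from
    presence-background distribution-model ensembles with AUC-weighted
    consensus and two-sided confidence-limit maps, and calculates the Red
    List Index with bootstrap confidence limits, multi-group and sampled
    variants. Includes a synthetic-landscape and virtual-species generator
    for offline testing, readers and writers for occurrence CSV, ESRI
    ASCII grid, GeoTIFF, GeoJSON boundaries and KML, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    xml2
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    pROC,
    mgcv,
    ape,
    png
Config/testthat/edition: 3
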