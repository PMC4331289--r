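Package: cropclassr
Title: Parcel-Level Crop Classification from Multitemporal Imagery with
    CART Rule Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-phase pipeline for classifying agricultural census parcels
    from a time series of co-registered multispectral images. Phase one
    extracts per-parcel mean digital numbers for the Blue, Green, Red and
    NIR bands plus three vegetation indices (NDVI, stubble index R/G, and
    B/G) at every acquisition, assembling a parcels-by-features matrix.
    Phase two trains a CART decision tree (Gini impurity, depth and node
    size limits, stratified cross-validated risk), exports every terminal
    node as an SQL predicate rule, and applies the rule models to label
    unidentified parcels, with confusion-matrix accuracy assessment
    (user's, producer's and overall accuracy). A synthetic phenology-driven
    scene generator produces TIFF rasters and GeoJSON parcels with known
    labels so the whole pipeline can be exercised without satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    rpart,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
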