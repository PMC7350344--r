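Package: rootmorph
Title: Automated Root Morphology Phenotyping from Tray Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for root system architecture phenotyping
    of washed root systems photographed on a bright tray. Multi-exposure image
    stacks are median-projected, the bright tray frame is detected with a Hough
    line transform and cropped away, root pixels are segmented with a Gaussian
    mixture model fitted by expectation-maximisation and classified by posterior
    probability, dirt particles are removed by connected-component shape
    criteria, and root length per diameter class is measured from the medial
    axis and the Euclidean distance transform. Per plant, diameter-length
    histograms are cumulated over trays, split into fibrous and storage roots
    with Otsu's method, and converted to length, volume, surface area and mean
    radius under a cylinder geometry. A synthetic tray generator with exact
    centerline ground truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
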