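Package: dgfseg
Title: Tongue Image Segmentation by the Double Geo-Vector Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic segmentation of the tongue body in clinical-style face
    photographs using the double geo-vector flow (DGF): a saliency window
    localizes the mouth region, four anatomical feature points (two mouth
    corners, tongue tip, tongue root) seed an initial contour, a
    distance-regularized geodesic level-set flow evolves the lower tongue
    boundary, and a gradient-vector-flow snake with a geometric propulsion
    term, driven by a binarized map of the dark mouth opening, evolves the
    upper boundary. Includes boundary (Hausdorff, mean distance) and area
    (false-positive, false-negative, true-positive volume fraction) error
    metrics, a deterministic synthetic tongue-scene generator with
    pixel-perfect ground truth, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jpeg,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
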