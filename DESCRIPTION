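Package: capseg
Title: Depth-Guided Detection, Segmentation and Tracking of Mushroom Caps in RGB-D Bed Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometry-driven instance segmentation and multi-frame tracking of
    white button mushrooms (Agaricus bisporus) in dense cultivation beds imaged
    with a registered RGB-D camera. Overlapping rail frames are stitched into a
    mosaic by normalized cross-correlation template matching; depth is converted
    to a background-homogenized elevation map; cap apices are detected as local
    elevation maxima; per-cap boundaries are estimated by radial depth-gradient
    analysis over concentric square rings with inflection-based limits where
    caps touch, refined in three filtering passes, and rasterized as convex-hull
    masks; multiply-claimed pixels are resolved by a depth-guided
    marker-controlled watershed; identities are maintained across time-lapse
    frames by IoU-based optimal (Hungarian) assignment. Includes a seeded
    synthetic RGB-D bed generator with exact ground truth, detection /
    segmentation / tracking metrics, ggplot2 visualization helpers, and a thin
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    yaml,
    tiff,
    png,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    tidyr
Config/testthat/edition: 3
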