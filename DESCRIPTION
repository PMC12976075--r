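Package: slideseg
Title: Pan-Cancer Tumour Segmentation in Whole-Slide Histopathology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of an automatic tumour-segmentation
    pipeline for haematoxylin-and-eosin stained whole-slide images: pyramid
    reading with micrometre-per-pixel targeted downsampling, equal-overlap
    tiling, Canny/morphology tissue masking, dataset balancing and channel
    standardisation, a pluggable encoder-decoder segmentation network with
    Dice plus top-90 cross-entropy loss, distance-weighted mosaic stitching,
    hysteresis post-processing with connected-component pruning, and a full
    pixel-, cohort- and region-level evaluation suite. Ships a deterministic
    synthetic-slide generator so the whole pipeline is exercisable end to end
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    jpeg,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
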