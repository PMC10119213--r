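Package: spheroidquant
Title: Quantification of 3D Spheroid Invasion Cultures from Fluorescence Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-quantification workflow for 3D tumor-spheroid invasion cultures
    imaged by confocal microscopy of a nuclear reporter (H2B-GFP-like channel).
    Implements per-slice nucleus segmentation (Gaussian preprocessing, Phansalkar
    local adaptive thresholding, binary median filtering, watershed separation,
    calibrated area filtering), partitioning of each slice into spheroid core,
    rim and invasion zone with random-quadrant subsampling, radial invasion
    distance metrics, apoptosis scoring from clustered nuclear fragments,
    mitosis-annotation ingestion, signal-to-noise-versus-depth profiling for
    optically cleared versus uncleared specimens, an exact Mann-Whitney U test
    for two-group comparisons, and a calibrated synthetic spheroid image
    generator with exported ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: CellBiology, Visualization, Preprocessing
RoxygenNote: 7.3.3
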