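Package: plantrecon
Title: Benchmarking 3D Plant Reconstructions Against Laser-Scan Ground Truth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Evaluates image-based 3D plant reconstructions (for example point
    clouds exported from radiance-field models) against terrestrial laser scans.
    Provides point-cloud reading, writing, cropping and cleanup (PLY, PCD, XYZ),
    correspondence-based similarity alignment and multiscale iterative-closest-point
    refinement, distance-threshold precision/recall/F-score with per-point
    Correct/Missing/Outlier labeling and precision-recall curves, classical and
    perceptual 2D image metrics (MSE, PSNR, SSIM, LPIPS with a pluggable feature
    backbone), plateau detection on perceptual-metric training curves for early
    stopping of radiance-field training, and seeded synthetic fixtures (plant-like
    surface clouds, degraded copies, decay curves, image pairs) so the whole
    pipeline is testable without GPUs or captured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    withr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
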