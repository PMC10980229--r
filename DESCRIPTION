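Package: axontune
Title: Fine-Tuning 3D U-Nets for Axon Segmentation in Sparsely Annotated Light-Sheet Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for fine-tuning small 3D U-Net models to segment axons in
    light-sheet fluorescence microscopy volumes where expert annotation exists
    only on periodic z-slices. Provides a synthetic tubular-filament phantom
    generator, one-pixel axon edge-class generation, foreground-oversampled
    patch sampling with geometry-consistent spatial and intensity augmentation,
    a class-weighted masked cross-entropy loss that excludes unlabeled slices,
    configurable layer freezing for transfer learning, Gaussian-weighted
    overlapping sliding-window inference, edge-tolerant evaluation metrics
    (edge precision and edge F1), and an ablation harness with a
    half-standard-deviation selection rule for choosing training modifications.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
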