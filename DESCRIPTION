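Package: pseudocell
Title: Self-Supervised Pseudo-Colorization of Masked Cells and
    Centroid-Heatmap Cell Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-supervised pre-training for fluorescence microscopy by
    reconstructing pseudo-colorized, partially masked cell images, together
    with the centroid-heatmap detector that the pretext task pre-trains.
    Provides pseudo-spectral colormap lookup tables and perceived-brightness
    profiles, a padded patch-masking scheme alongside MAE-style masking, a
    centroid-heatmap/size-map label codec with image-moment decoding, a
    hybrid CNN detector with a prepended slice-context block for 2.5D
    analysis of 3D stacks, training losses and similarity metrics, a seeded
    generator of fluorescence-like synthetic scenes with exact ground truth,
    and pre-training/training/evaluation pipelines with a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
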