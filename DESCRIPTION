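Package: toothcutter
Title: Bitewing Radiograph Segmentation and Caries/Restoration Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end toolkit for analysing dental bitewing radiographs.
    Raw films are enhanced by frequency-domain Gaussian high-pass filtering
    and subtraction, binarized with Otsu's method, and segmented into
    single-tooth half images by rotation-optimized integral projection
    profiles with oblique separating lines and half-plane masking. Labeled
    half-tooth images are assembled into balanced per-finding databases
    (augmentation of the minority class, subsampling of the majority), and a
    modified AlexNet convolutional network trained by mini-batch stochastic
    gradient descent with momentum judges caries and restorations per tooth
    side. A synthetic bitewing generator with exhaustive ground truth makes
    every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
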