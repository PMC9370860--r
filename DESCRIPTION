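Package: pomseg
Title: Multi-Stage Pseudo-Labeling for Fruit Segmentation in Orchard Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised pixel-wise segmentation of fruit (pomegranate-style)
    versus background in orchard imagery. Implements automatic mask generation
    for controlled-environment photographs (RGB colour thresholding followed by
    connected-component noise removal, eccentricity-based stem discarding and
    hole filling), a deterministic 20-fold paired image/mask augmentation
    scheme, a compact trainable segmentation network with a multi-scale dilated
    pooling feature pyramid, and the three-stage pseudo-labeling training
    cascade (controlled-environment net, true-negative-augmented net,
    field-image-augmented net) together with the full pixel-wise evaluation
    suite (precision, recall, F1, global and mean accuracy, mean and weighted
    IoU, four-colour error maps). A seeded synthetic scene generator provides
    exact ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
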