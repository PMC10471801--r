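Package: fieldlines
Title: Farmland Boundary Segmentation and Line Extraction from Aerial Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage extraction of farmland boundary lines from aerial RGB
    orthoimage tiles. Stage one is a lightweight encoder-decoder semantic
    segmentation network (a MobileNetV2 backbone with a convolutional block
    attention module, feeding an atrous spatial pyramid pooling head augmented
    with a strip-pooling branch and a DeeplabV3+ style decoder) that labels
    each pixel as crop, bare soil or background; the network, its Dice-loss
    training loop with a cosine-annealed learning rate, and confusion-matrix
    segmentation metrics (pixel accuracy, mPA, mIoU) are implemented in R with
    compiled kernels. Stage two turns a class mask into field boundary lines:
    morphological cleaning, 8-connected region labelling with small-region
    exclusion, Moore-neighbour boundary tracing, orientation-aware splitting of
    boundary points, and least-squares line fitting with standardized-residual
    outlier rejection, scored by angular and vertical error against known
    lines. A seeded synthetic-scene generator provides images, exact masks and
    ground-truth boundary lines so the whole pipeline is testable without
    field data.
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
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
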