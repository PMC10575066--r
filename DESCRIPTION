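Package: segens
Title: Ensemble UNet Semantic Segmentation of Crops in RGB and HSV Color
    Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Trains small encoder-decoder (UNet) segmentation networks on
    complementary color-space views (RGB and HSV) of field scenes, combines
    them under a bagging-style ensemble with a weighted binary cross-entropy
    loss, and fuses member probability maps pixel-wise into a binary
    crop/background mask.  Includes a synthetic field-scene generator with
    ground-truth masks, paired image/mask augmentation with synchronized
    geometric transforms, a 7:2:1 dataset splitter, IoU and pixel-accuracy
    evaluation, polygon-annotation import, and a command-line interface
    covering scene simulation, data preparation, training, prediction and
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jpeg,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
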