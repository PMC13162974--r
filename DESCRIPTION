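Package: wavesam
Title: Lightweight Promptable Polyp Segmentation with Wavelet Channel
    Attention and Efficient Channel Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A promptable encoder-decoder segmentation network for endoscopic
    polyp images, built from a compressed ViT-S/16 image encoder, a mask-prompt
    encoder fed by morphologically eroded coarse masks, and a progressive
    transposed-convolution mask decoder. Two lightweight feature-enhancement
    blocks are provided: a Haar-wavelet subband channel-cooperative attention
    block applied to the raw image, and a depthwise-separable convolution block
    with efficient channel attention applied after patch embedding. The package
    includes a self-contained reverse-mode autodiff core, the composite
    Dice + binary cross-entropy training objective with Adam, cosine annealing
    and gradient clipping, synchronized geometric augmentation, overlap metrics,
    a synthetic endoscopy-scene generator for download-free testing, and exact
    trainable-parameter and multiply-accumulate budget accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
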