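Package: tmscodec
Title: Tunable Multi-Scale Learned Lossless Compression for Grayscale Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lossless compression of 8-bit single-channel (medical-style)
    images with a tunable multi-scale scheme: polyphase quadtree partitioning
    into four subimages, an anchor subimage coded by a conventional codec
    (PNG, or JPEG-XL when available), and the remaining subimages coded by
    neural residual prediction with a 511-class per-pixel probability model
    fed to an arithmetic coder. Each subimage can take a fast route (one
    whole-plane network pass) or a slow route (column-masked two-stage
    refinement that conditions on the already-coded even columns), trading
    speed against bits per pixel. Includes the network definitions (ResBlock
    feature extractor, squeeze-and-excitation attention UNet probability
    head) with a self-contained reverse-mode autodiff tape and Adam trainer,
    a seeded synthetic image generator (smooth, textured, speckle regimes),
    and evaluation tools (bits per pixel, probability heatmaps, probability
    bin reports).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    stats,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
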