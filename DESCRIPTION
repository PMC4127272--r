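Package: sbpnn
Title: Spectral Subband Neural Transform Coding for Grayscale Biomedical Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compression and decompression of 8-bit grayscale biomedical
    images by run-length (cosimilar pair-value) coding combined with an
    autoassociative feed-forward neural network transform coder, applied
    either directly to pixel runs or to the subbands of a pyramidal
    discrete wavelet decomposition (spectral mode). Includes a lossless
    mode, a self-describing binary container format, an evaluation harness
    (compression ratio, PSNR, timing) with a pluggable external baseline,
    and a seeded generator of anatomical-phantom test images with
    controllable run-length redundancy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    tiff,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
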