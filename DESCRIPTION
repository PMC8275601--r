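Package: usblur
Title: Motion-Blur Invariants and Blind Restoration for Ultrasound Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models linear motion blur in B-mode ultrasound images with a
    discrete line-segment point-spread function, derives blur-invariant
    features in the frequency domain (sinc-ratio invariants) and in the
    geometric-moment domain (moment convolution relations), estimates the
    motion angle and length blindly from the periodic zero lines of the
    log-magnitude spectrum of a single blurred image, and restores images
    by Wiener deconvolution. Ships an ultrasound-like speckle phantom
    generator so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, png, tiff, EBImage, withr
Suggests: testthat (>= 3.0.0), jpeg, jsonlite, optparse
biocViews: ImageProcessing, Visualization, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'utils.R'
    'psf.R'
    'freqInvariants.R'
    'moments.R'
    'blind.R'
    'restoration.R'
    'quality.R'
    'synthetic.R'
    'io.R'
    'usblur-package.R'
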