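Package: dermafuse
Title: Contrast Enhancement, Feature Fusion and Marine-Predator Feature
    Selection for Dermoscopic Lesion Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the bespoke computational stages of a dermoscopic
    skin-lesion recognition pipeline: luminance/Retinex contrast enhancement
    driven by a Gaussian texture residual and a lesion activation mask;
    serial-harmonic-mean fusion of two per-sample deep-feature matrices using
    maximum rank-correlation scores and a harmonic-mean threshold; wrapper
    feature selection by the Marine Predator Algorithm gated by Renyi entropy
    with a k-nearest-neighbour fitness; multiclass evaluation with standard
    classifiers and macro-averaged metrics; and seeded generators for
    lesion-like images and planted-structure feature datasets so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    png,
    jsonlite,
    e1071,
    rpart,
    nnet
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
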