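Package: hpcsi
Title: Hyperpolarized 13C MRSI Quantification for Preclinical Brain Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for quantifying hyperpolarized [1-13C] pyruvate
    chemical shift imaging (CSI) of the rodent brain: simulation of dynamic
    2D CSI acquisitions from digital tissue phantoms with known two-site
    pyruvate-lactate exchange kinetics, k-space reconstruction with
    zero-filling, Lorentzian lineshape fitting of time-summed voxel spectra,
    lactate-to-pyruvate AUC ratio maps, hemisphere region-of-interest
    summaries with percent-of-contralateral normalization, anatomical label
    volumetry, and the group-comparison statistics layer (one-way, two-way
    and repeated-measures ANOVA with Tukey HSD post-hoc correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    minpack.lm,
    RNifti,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
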