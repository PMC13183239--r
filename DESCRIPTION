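Package: vitispec
Title: Leaf Reflectance Spectroscopy and Trait Variation Analysis for
    Grapevine Cultivars
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying intraspecific leaf trait variation across
    a cultivar hierarchy and predicting traits from full-range (400-2400 nm)
    leaf reflectance spectra.  Provides a from-scratch NIPALS partial least
    squares regression (PLSR) engine with variable-importance-in-projection
    (VIP) scores, leave-one-out PRESS component selection, repeated-subsample
    jackknife uncertainty estimates, and two calibration/validation
    data-splitting regimes; nested variance-component partitioning across
    origin, colour, cultivar and planting row; trait derivation, normality
    screening and interquartile-range outlier filtering; a cultivar-structured
    synthetic vineyard generator with trait-linked absorption features; and a
    configurable end-to-end pipeline with a command-line entry point.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
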