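Package: metabarcode
Title: Pixelated High-Q Metasurface Biospectroscopy with Explainable CNN Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for surface-enhanced infrared
    absorption (SEIRA) biospectroscopy on pixelated high-Q metasurfaces. Provides
    a forward model for metapixel reflectance spectra (temporal coupled-mode Fano
    lineshapes with Lorentzian molecular loss channels and D2O medium
    attenuation), photoisomerization kinetics of azobenzene photolipid membranes
    under LED switching schedules, barcode layout construction with pixel
    doubling and seeded randomization, hyperspectral-cube spectral extraction and
    absorbance retrieval, and a one-dimensional convolutional neural network
    classifier of cis/trans membrane states with integrated-gradients feature
    attribution, metapixel selection, and a pruned single-metapixel model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    rlang
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
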