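Package: carpetFCS
Title: Pair Correlation Function Analysis of Line-Scan Fluorescence Carpets
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Fluctuation spectroscopy of confocal line-scan "carpets"
    (successive scan lines stacked in time). Provides per-pixel
    autocorrelation and spatial pair cross-correlation (pCF) at arbitrary
    pixel separations on a multi-tau lag grid, closed-form diffusion models
    for a 3D Gaussian focal volume with nonlinear fitting of D and N,
    PSF calibration, transit-delay extraction and barrier detection along
    the scanned line, and a Brownian-dynamics simulator of two-compartment
    (nucleus/cytoplasm) transport with a semi-permeable envelope, passive
    and carrier-like directional crossing, Gaussian-PSF scanning and
    Poisson photon detection, so the whole pipeline can be validated
    end-to-end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    Rcpp,
    minpack.lm,
    jsonlite,
    tiff,
    data.table,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: FluorescenceCorrelationSpectroscopy, Software, Spectroscopy
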