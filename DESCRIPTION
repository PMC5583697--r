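Package: pwsld
Title: Disorder-Strength Mapping for Partial Wave Spectroscopic Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for partial wave spectroscopic (PWS)
    nanocytology. Converts wavelength-resolved reflectance image cubes
    R(x,y,lambda) into per-pixel spectral-variance (Sigma) and disorder
    strength (L_d) maps via zero-phase Butterworth denoising, polynomial
    baseline removal and thickness normalisation; segments nuclei in
    transmission images with maximum-entropy (Kapur) thresholding and
    marker-controlled watershed; and compares patient cohorts by
    cumulative-SD effect size and significance tests. Ships a 1D
    transfer-matrix wave-optics simulator for Gaussian-correlated random
    media and a 2D cell-phantom generator with ground-truth masks, so the
    whole pipeline is testable end to end without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    signal,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
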