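Package: airaqua
Title: Baseline-Corrected Absolute Quantification for Targeted 1D 1H NMR
    Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for targeted proton NMR metabolomics of complex samples
    with broad background signals, such as plant root exudates. Implements
    adaptive iteratively reweighted penalized least squares (airPLS) baseline
    correction with region-specific smoothing factors on top of a sparse
    Whittaker smoother, absolute quantification of a preselected metabolite
    panel from one reporter signal per metabolite with linear interference
    correction against a Lorentzian signal library, an internal-standard
    calibration route, a background-extraction algorithm for constructing
    smooth spectral background models from experimental spectra, and
    simulation and spike-in evaluation machinery reporting regression
    statistics, percent differences and limits of quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
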