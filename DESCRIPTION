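Package: bilayertools
Title: Analysis of Lipid Bilayer Modification Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis chain for membrane-biophysics studies of
    small-molecule action on lipid bilayers and reconstituted ion channels:
    conversion of carrier-mediated conductance to boundary-potential changes
    via the Boltzmann relation, Langmuir adsorption-isotherm fitting
    (nonlinear and linearized), ratiometric dipole-potential estimation,
    differential scanning calorimetry feature extraction and van't Hoff
    deconvolution, calcein-leakage quantification, single-channel trace
    idealization with conductance and dwell-time statistics, Fisher-transform
    correlation screening of physicochemical descriptors against membrane
    effects, and a synthetic-data module that emulates all five assay types
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    signal,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
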