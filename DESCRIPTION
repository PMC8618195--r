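Package: brams
Title: Chemo-Mechanical Analysis of Brillouin-Raman Micro-Spectroscopy Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for correlative Brillouin-Raman micro-spectroscopy (BRmS)
    of mineralised tissue. Per-pixel Brillouin spectra are decomposed into a
    soft (disordered matrix, marrow) and a hard (mineralised collagen) phase
    via fit-free spectral moments; band intensities are normalised into
    relative volume fractions, converted to longitudinal elastic moduli and
    combined into a Voigt-averaged modulus. Raman spectra are baseline
    corrected, normalised to the 1445 cm-1 CH2 band and summarised by
    mineral-to-matrix, lipid-to-protein and heme-to-amide markers, with PCA of
    the fingerprint region for classification. Includes region-of-interest
    statistics, percent-change comparisons, and a synthetic cortical and
    trabecular bone phantom generator with per-pixel ground truth for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'constructors.R'
    'brillouin.R'
    'raman.R'
    'chemometrics.R'
    'mapping.R'
    'methods.R'
    'spectral_io.R'
    'synthetic.R'
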