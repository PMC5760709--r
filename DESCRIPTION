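Package: memphys
Title: Membrane Biophysics Analysis: FRAP, Laurdan GP Imaging, AFM Force
    Spectroscopy and Per-Cell Image Quantification
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of plasma-membrane biophysics experiments
    comparing control and glycosphingolipid-enriched (Gaucher-model) cells.
    Implements double normalization and empirical model fitting of
    fluorescence recovery after photobleaching (FRAP) curves, steady-state
    fluorescence anisotropy and Laurdan generalized polarization,
    generalized-polarization image mapping and high/low-order domain
    segmentation with a shared pooled threshold, atomic force microscopy
    force-curve analysis (contact-point detection, pyramidal-tip Hertz
    fitting, dual-algorithm membrane-tether step detection and tether
    statistics), and per-cell quantification of endocytosed ligand and
    nuclear STAT1 fractions from multi-channel images via marker-controlled
    watershed segmentation. A synthetic-data generator with named presets
    produces every input modality with known ground truth so each analysis
    stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    EBImage,
    minpack.lm,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
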