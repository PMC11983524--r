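Package: ramanband
Title: Raman and NIR-Autofluorescence Spectral Band Imaging Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for wide-field Raman spectral band imaging of tissue in
    the presence of a dominant near-infrared autofluorescence background.
    Implements iterative polynomial baseline decomposition of single-point
    Raman spectra, spectrally guided separation of Raman band images
    (1437 and 1655 cm-1) from autofluorescence via a calibration constant k,
    gray-level co-occurrence and histogram texture features from image
    patches, and multi-classifier tissue-class evaluation with repeated
    holdout and cumulated confusion matrices. Includes a synthetic optical
    phantom generator with known ground truth so the whole pipeline can be
    exercised and validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    e1071,
    rpart,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
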