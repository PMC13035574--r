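Package: esohsi
Title: Hyperspectral Imaging Analysis of Esophagogastric Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of intraoperative hyperspectral imaging
    (HSI) of esophagogastric specimens. Generates annotated phantom
    hyperspectral cubes from Beer-Lambert chromophore templates, reads and
    writes ENVI cubes and PNG annotation masks, preprocesses spectra (spectral
    median filter, standard normal variate, wavelength cropping), computes
    physiological index maps (StO2, NIR-PI, TWI, OHI), classifies tissue
    pixel-wise with a hybrid 3D-1D convolutional network under
    leave-one-patient-out cross-validation, reports patient-wise metrics
    (sensitivity, specificity, F1, MCC, ROC-AUC), and compares physiological
    parameters between tissue classes and tumor-stage groups with Welch
    t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
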