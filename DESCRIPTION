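Package: loquatHSI
Title: Hyperspectral Chemometrics for Loquat Quality and Maturity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A chemometric pipeline for hyperspectral assessment of loquat
    fruit quality (colour e value, firmness, soluble solids content) and
    maturity stage. Covers ENVI cube input/output, black/white reflectance
    correction, fruit segmentation, standard normal variate preprocessing,
    SPXY and Kennard-Stone calibration splitting, wavelength selection by
    competitive adaptive reweighted sampling (CARS), a genetic algorithm
    and the successive projections algorithm, calibration by PLSR, PCR,
    MLR, extreme learning machine and back-propagation network, maturity
    discrimination by PLS-DA, nearest-class-centroid and SVM, and
    pixel-wise pseudo-colour quality maps with deviation compression.
    Includes a synthetic-data generator emulating loquat reflectance
    spectra so that every step is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    png,
    e1071,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    nnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'classify.R'
    'cube-ops.R'
    'envi-io.R'
    'evaluate.R'
    'loquatHSI-package.R'
    'models-fit.R'
    'models-published.R'
    'pipeline.R'
    'pls-engine.R'
    'preprocess.R'
    'quality-reference.R'
    'select-cars.R'
    'select-common.R'
    'select-ga.R'
    'select-spa.R'
    'splits.R'
    'synthetic.R'
    'visualize.R'
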