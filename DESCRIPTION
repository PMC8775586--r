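Package: uvscene
Title: Natural Image Statistics for Dichromatic UV/Green Visual Scenes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the first- and second-order statistics of
    co-acquired ultraviolet and green images of natural scenes, as seen by a
    dichromatic visual system such as the mouse retina. Provides photoreceptor
    spectral-sensitivity modelling (visual pigment nomogram, ocular
    transmittance correction, photon-budget and angular-sampling estimates),
    preprocessing of paired two-camera captures (flat-field vignetting
    correction, median filtering, projective registration, cropping,
    normalization), Laplacian-of-Gaussian local contrast with two-parameter
    Weibull fits, circular-patch RMS and chromatic contrast, power-spectrum
    slope estimation and FFT-based spatial autocorrelation, paired sign and
    rank-sum channel comparisons, and a synthetic two-channel scene generator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    png,
    digest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'compare-report.R'
    'utils.R'
    'firstorder-stats.R'
    'patch-stats.R'
    'secondorder-stats.R'
    'preprocess.R'
    'pipeline.R'
    'png-io.R'
    'spectral-model.R'
    'synthetic-scenes.R'
    'uvscene-package.R'
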