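Package: nirsdot
Title: fNIRS Channel-Space Analysis and Diffuse Optical Tomography on the
    Cortical Surface
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for continuous-wave functional near-infrared spectroscopy
    (fNIRS): SNIRF and Homer file input/output, channel quality assessment
    (scalp coupling index, coefficient of variation), motion correction
    (spline interpolation and temporal derivative distribution repair),
    frequency filtering, short-separation regression, conversion to
    hemoglobin concentration changes via the modified Beer-Lambert law,
    general linear model activation analysis with AR(1) prewhitening or
    precoloring, analytic channel sensitivity modelling with Voronoi
    volume-to-surface projection and montage overlap metrics, depth-weighted
    minimum-norm and maximum-entropy-on-the-mean (cMEM) tomographic
    reconstruction, optimal optode placement by exact integer optimisation,
    and a layered-sphere phantom simulation harness with spatial-dispersion
    and ROC-AUC validation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    rhdf5,
    RNifti,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cmem.R'
    'extinction.R'
    'forward.R'
    'glm.R'
    'io-misc.R'
    'io-nirs.R'
    'io-snirf.R'
    'mne.R'
    'montage.R'
    'phantom.R'
    'pipeline.R'
    'preprocess.R'
    'probe.R'
    'quality.R'
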