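Package: icsfilter
Title: Image-Space Compensation of Inter-Crystal Scattering in PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling and correcting inter-crystal scattering
    (ICS) in positron emission tomography entirely in image space. A Monte
    Carlo detector simulator traces 511 keV photon pairs through a ring of
    scintillator crystals (Compton, Rayleigh and photoelectric interactions)
    to produce ICS-affected line-of-response histograms; a small multilayer
    perceptron learns position-dependent 11x11x11 image-space blur kernels,
    either directly or through a rotated 3D skew-normal parameterization;
    the kernels are applied to the image estimate before each OS-EM forward
    projection to compensate the resolution loss caused by ICS. Includes a
    matched Siddon forward/backprojector pair, Derenzo/point/cylinder
    phantom generators, a LOR-space reference correction, and NRMSE-based
    evaluation of reconstructions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp (>= 1.0.0),
    Matrix,
    jsonlite,
    yaml,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'geometry.R'
    'io.R'
    'attenuation.R'
    'phantoms.R'
    'mc.R'
    'projector.R'
    'skewnorm.R'
    'icsnet.R'
    'training.R'
    'reconstruction.R'
    'experiment.R'
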