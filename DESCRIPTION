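Package: cinestrain
Title: Automated Left-Ventricular Segmentation, Volumetry and
    Circumferential Strain from Cine Cardiac MR
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fully automatic analysis engine for balanced-SSFP cine cardiac
    magnetic resonance studies. Detects the left-ventricular blood pool as a
    bright moving round object, fits the time-resolved mitral-valve base
    plane from long-axis views, computes dense inverse-consistent
    deformation fields between cardiac phases by local cross-correlation
    registration, recovers temporally consistent endocardial and epicardial
    contours by shortest closed paths in polar space, and derives cavity
    volumes, ejection fraction, and mean mid-wall Lagrangian circumferential
    strain. Includes a synthetic deformable cardiac phantom with analytic
    ground-truth motion, strain, volumes and valve plane for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Rcpp,
    EBImage,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
biocViews: Software, ImageSegmentation, CardiovascularImaging
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'cinestrain-package.R'
    'utils.R'
    'data_io.R'
    'localization.R'
    'phantom.R'
    'registration.R'
    'strain.R'
    'segmentation.R'
    'pipeline.R'
    'volumetrics.R'
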