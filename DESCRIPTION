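Package: orbvol
Title: Semi-Automatic Orbital Cavity Volumetry from CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures the volume of the bony orbit on computed-tomography
    scans by a semi-automatic pipeline: an over-inclusive seeded cavity
    segmentation is refined by subtracting Hounsfield-unit bone (>= +400 HU)
    and air (<= -600 HU) masks, clipped at an anterior boundary surface
    fanned through rim landmarks and their centroid, and reduced to its
    largest connected component. Ships the full validation battery (volume
    in cc, Dice coefficient, signed surface-distance maps, two-way random
    absolute-agreement ICC with 95 percent confidence interval, paired t
    test) and a deterministic synthetic orbit phantom with a closed-form
    ground-truth volume so the whole pipeline is testable without clinical
    data. Reads DICOM series and NIfTI volumes, landmark CSV/JSON, and
    writes NIfTI masks, JSON reports and STL surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'mask-ops.R'
    'anterior.R'
    'phantom.R'
    'metrics.R'
    'segmentation.R'
    'io.R'
    'cli.R'
    'io-dicom.R'
    'orbvol-package.R'
    'show-methods.R'
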