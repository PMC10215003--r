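Package: cccmr
Title: Collapsed Cone Convolution/Superposition Dose Engine with
    Density-Specific Kernels for Transverse Magnetic Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Photon dose calculation for magnetic resonance-guided
    radiotherapy. Generates three-dimensional, magnetic-field-distorted
    energy deposition kernels in water of arbitrary mass density with a
    built-in Monte Carlo engine, and superposes TERMA with a collapsed
    cone algorithm whose inhomogeneity correction combines density
    scaling with kernel selection indexed by the average mass density
    between interaction and deposition points. Includes voxel phantom
    builders, a point-source beam and spectrum-fitting model, and a
    validation stack with percentage depth dose and off-axis profiles,
    TG-53 region segmentation and three-dimensional gamma analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
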