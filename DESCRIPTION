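Package: sset
Title: Serial-Section Electron Tomography Alignment, Restoration and
    Synapse Morphometrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for assembling continuous volumes from serial-section
    electron tomography (ssET). Propagates region-of-interest stage
    positions across sections with a staged affine scheme, aligns
    consecutive tomographic volumes coarse-to-fine (multi-resolution
    feature matching with robust affine estimation, then grid block
    matching corrected by belief propagation and interpolated with thin
    plate splines), estimates the number of slices lost between volumes
    from section thickness bookkeeping and intensity sensitivity maps,
    synthesises the missing slices with an optical-flow frame
    interpolator (with a distillation-trained student variant), and
    segments and measures synaptic ultrastructures (membranes via
    affinity-map watershed, vesicles via ROI-restricted detection).
    Ships a phantom generator with exact ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
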