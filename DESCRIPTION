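Package: MARbench
Title: Quantitative Phantom-Based Benchmarking of CT Metal Artifact
    Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A quantitative framework for benchmarking CT metal artifact
    reduction (MAR) algorithms with a cylindrical single-insert phantom.
    Implements circular CT-number profile analysis at fixed radii around a
    metal insert, threshold-based geometric accuracy of the reconstructed
    insert, annular bad-voxel statistics with the composite M-error index,
    CT-number difference maps with percentile clipping, and cumulative
    delta-CTN histograms. Ships a parallel-beam polychromatic CT simulator
    with Poisson noise and photon starvation plus a reference
    sinogram-inpainting MAR, so the whole metric suite is testable
    end-to-end without scanner data. Reads DICOM CT series and a portable
    NIfTI volume container.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
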