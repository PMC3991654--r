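Package: acmap
Title: Anatomical Connectivity Mapping for Diffusion MRI
Version: 0.1.0
Authors@R:
    person("ACM", "Maintainers", email = "maintainers@acmap.invalid",
           role = c("aut", "cre"))
Description: Spatially normalized anatomical connectivity mapping (ACM) from
    diffusion-weighted MRI. Fits single- and two-tensor fiber models per
    voxel, warps tensor fields into a common atlas space with
    preservation-of-principal-direction (PPD) reorientation, calibrates
    Bingham fiber-orientation uncertainty from tensor shape and SNR (PICo),
    propagates probabilistic streamlines from every brain voxel, and counts
    per-voxel streamline visits to form connectivity maps. Includes the
    accompanying group-level statistical layer (voxel-wise GLM with
    permutation small-volume family-wise-error correction, ROI medians,
    disability correlations, lesion probability maps, Dice overlap) and a
    synthetic phantom/cohort generator so the full pipeline is testable
    without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
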