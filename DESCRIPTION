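Package: inhibitoryAtlas
Title: Consistent Estimation of Inhibitory Neuron Densities in Annotated
    Brain Volumes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates per-region densities of GABAergic neuron types
    (GAD67+, PV+, SST+, VIP+ and the residual population) in a voxelized,
    hierarchically annotated brain volume. Literature density records are
    normalized to per-region counts, marker expression volumes are converted
    to region mean intensities and mapped to densities through fitted linear
    transfer functions, and the resulting unconstrained estimates are
    reconciled into hierarchy-consistent counts by a weighted-slack linear
    program. Consistent counts are finally converted into explicit 3D cell
    positions by acceptance-rejection sampling. Synthetic toy brains with
    known ground truth support end-to-end validation, literature-subsampling
    and hold-out experiments.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    EBImage,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
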