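Package: synaptarch
Title: Nanoscale Architecture of Inhibitory Synapses from Localization
    Microscopy and Structured Illumination Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the nanoscale organization of synaptic proteins from
    single-molecule localization microscopy (dSTORM) and 3D structured
    illumination (3D-SIM) data. Covers the full post-processing chain:
    temporal quantile background filtering, wavelet spot detection and
    integrated-Gaussian sub-pixel fitting of raw frame stacks; quality
    filtering and temporal merging of localization tables; bead-based
    two-channel registration with polynomial or locally weighted displacement
    fields; redundant cross-correlation drift correction; average-shifted
    histogram and Gaussian pseudo-SIM rendering; density-based detection of
    high-density regions (HDRs) against a Monte-Carlo uniform-randomization
    null with alpha-shape boundary delineation and overlap classification;
    and geometric analysis of subsynaptic domains (SSDs) in labeled 3D
    volumes. A synthetic-data generator with full ground truth makes every
    stage testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
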