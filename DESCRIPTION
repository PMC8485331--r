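Package: chipsorb
Title: Compound Sorption Analysis for Perfused Microfluidic Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of small-molecule sorption in
    barrier-on-chip-type microfluidic circuits. Provides design equations for
    channel wall shear stress, wetted areas and surface-area-to-volume ratios;
    a partition-diffusion model predicting compound recovery from PDMS
    exposure; pseudo-sigmoidal fluorescence calibration with safeguarded
    inversion; replicate recovery statistics with MOVER-R confidence-interval
    propagation, limit-of-quantification censoring and surface-area
    normalization; fixed-intercept log-log hydrophobicity trend regression and
    partial-least-squares variable-importance analysis over molecular
    descriptors; and a synthetic experiment generator with recoverable ground
    truth for end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
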