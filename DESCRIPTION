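Package: azphys
Title: Presynaptic Capacitance, Exocytosis Kinetics and Active-Zone STED
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for direct presynaptic recordings and
    two-color STED imaging of active zones at hippocampal mossy fiber
    terminals. Implements sine+DC (Lindau-Neher) membrane capacitance
    estimation by lock-in admittance inversion, readily-releasable-pool
    depletion and Hill-cooperativity fits, calcium-current IV and
    activation analysis, EPSC train and paired-pulse quantification,
    and an active-zone image-quantification pipeline (unsharp-mask
    segmentation, colocalization gating, background-subtracted intensity
    integrals, Richardson-Lucy deconvolution, cluster metrics and
    nearest-neighbor distances with per-animal aggregation). Ships
    synthetic-data generators (voltage-clamp traces from an exact
    circuit model; multi-channel STED-like fields with ground truth) so
    every stage is verifiable by parameter recovery, plus exact
    small-sample rank statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    EBImage,
    minpack.lm,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
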