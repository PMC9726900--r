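Package: remkin
Title: Kinetic Modelling of Nucleosome Sliding from Single-Molecule and
    Bulk Remodelling Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing the kinetics of ATP-dependent chromatin
    remodelling. Implements dwell-time (pause-time) models for
    multi-step DNA translocation (gamma and hypoexponential
    distributions, maximum-likelihood fitting, model selection, and
    hidden-step "unmasking" analysis), an event-driven stochastic
    simulator of stepwise nucleosome sliding with concerted exit-side
    DNA ejection, synthetic two-channel smFRET trace generation and a
    matching analysis pipeline (molecule selection, change-point
    segmentation, pause-time extraction, reversal detection, FRET
    population mixture fitting), bulk remodelling and binding curve
    fits (asymptotic-exponential real-time fluorescence assays and 1:1
    binding isotherms with probe depletion), and crosslinking
    mass-spectrometry utilities (region filtering and C-alpha distance
    satisfaction scoring against structural models).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    mclust,
    minpack.lm,
    seqinr,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    fitdistrplus,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
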