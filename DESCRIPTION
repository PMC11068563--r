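Package: mcubind
Title: Quantitative Biophysics of MCU/MCUb N-Terminal Domain Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for the solution biophysics and cell imaging
    assays used to characterize protein-protein interactions of the
    mitochondrial calcium uniporter (MCU) and its dominant-negative paralog
    MCUb through their matrix-facing N-terminal domains.  Implements
    tight-binding (ligand-depletion) titration fitting for fluorescence,
    microscale-thermophoresis and ANS-binding isotherms; multi-transition
    Boltzmann analysis of circular-dichroism thermal melts; NMR
    chemical-shift-perturbation statistics and global slow-exchange
    titration fits with a shared dissociation constant; Zimm-type
    molecular-weight determination from SEC-MALS chromatograms; Manders
    colocalization with Costes automatic thresholding; spectral FRET ratio
    analysis; and GCaMP6f calcium-trace processing.  Seeded synthetic-data
    generators emulate every supported input modality so each analyzer can
    be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    tiff,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
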