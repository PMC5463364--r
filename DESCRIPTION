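Package: cytoscreen
Title: Dual-Plate High-Throughput Screening Analysis for Cytokinin
    Receptor Agonists and Antagonists
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for dual-plate (screening + reference)
    384-well high-throughput screens of compounds acting on the
    Arabidopsis cytokinin receptor CRE1/AHK4 expressed in an E. coli
    beta-galactosidase reporter strain.  Implements RFU/OD600
    normalization, Z'-factor assay quality control, Sidak-corrected
    Welch tests against the DMSO internal-standard baseline, five-class
    hit sorting anchored to on-plate controls, detection of
    autofluorescent and fluorescence-quenching compounds on a parallel
    reference plate, growth-effect flags, and normalization of live-cell
    radioligand competition data for hit validation.  A calibrated
    synthetic plate generator reproduces the assay's printed control
    statistics so the whole pipeline can be exercised without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
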