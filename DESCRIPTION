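Package: platefdc
Title: Single-Platelet Mechanophenotyping by Deformability Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-platelet mechanophenotyping with
    real-time fluorescence deformability cytometry (RT-FDC): contour-based
    deformation and size measurement from bright-field frames, fluorescence
    gating with geometric-mean statistics and percent-positive fractions,
    per-condition summaries and fold changes across ex vivo anticoagulants,
    and confocal line-profile quantification of the platelet cytoskeleton
    (marginal-band tubulin ring diameter, subcortical F-actin enrichment).
    Includes a calibrated synthetic-population generator covering the five
    common ex vivo anticoagulants, TRAP-6 stimulation, latrunculin-B-like
    actin disruption and an MYH9-like macrothrombocytopenia phenotype, in
    both analytic (exact ellipse geometry) and rasterised (rendered frame)
    modes, for pipeline validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    rlang,
    withr,
    jsonlite,
    pracma,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2,
    tiff,
    png
Config/testthat/edition: 3
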