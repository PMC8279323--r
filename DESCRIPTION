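Package: archflow
Title: Patient-Specific Hemodynamic Modelling of the Cephalic Arch
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs three-dimensional cephalic-arch lumen geometry from
    venogram projections and intravascular-ultrasound (IVUS) cross-sections,
    simulates steady and pulsatile incompressible laminar blood flow through the
    reconstructed vessel, and derives the hemodynamic quantities used to study
    cephalic arch stenosis in brachiocephalic fistula patients: Reynolds
    numbers, velocity, pressure and wall-shear-stress fields, cell Reynolds
    numbers, and geometric or low-shear regions of interest. Includes a
    synthetic-data generator (venogram-like projections, IVUS-like contour
    stacks, idealized and stenosed arches, patient parameter records) so the
    full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    igraph,
    jsonlite,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
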