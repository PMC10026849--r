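Package: opcmap
Title: Lesion-Centered Spatial and Morphometric Quantification of
    Stroke-Responsive Oligodendrocyte Progenitor Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification pipeline for microscopy-derived readouts of the
    oligovascular niche after white-matter stroke: k-nearest-neighbor density
    maps of cell point patterns on a lesion-centered grid with permutation
    p-value maps and significant-region extraction; cell-to-vessel
    nearest-neighbor proximity and vessel-association summaries; bootstrap
    lesion-volume estimation from sparse serial-section areas; electron
    microscopy g-ratio statistics; raster vessel-network morphometry
    (skeleton length and junction counts); voxel colocalization and
    particle-filtered object measurements; and per-animal summarization
    with named group-comparison tests. A seeded synthetic-data module
    generates every input with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    EBImage,
    tiff,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
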