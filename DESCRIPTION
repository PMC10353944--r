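Package: nichemech
Title: Quantification of Adhesion Mechanics and Migration in the Neural Stem Cell Niche
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Image- and table-based quantification of cell-matrix adhesion
    mechanics and migration in the aging neural stem cell niche. Converts
    donor/acceptor micrograph pairs from molecular tension sensors into
    per-pixel FRET-efficiency and force maps, segments force-producing
    adhesions by watershed and summarizes per-cell force profiles; quantifies
    detachment, centrifugation and Matrigel dispersion assays; links
    time-lapse detections into migration tracks; measures distances of
    marker-classified cells to the ventricle border and counts cells in niche
    regions; scores single-cell gene-set signatures; and provides exact
    nonparametric group tests. A synthetic-data generator with known ground
    truth exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    Matrix,
    tiff,
    yaml
Suggests:
    fgsea,
    jsonlite,
    testthat (>= 3.0.0),
    withr
biocViews: CellBiology, Software, SingleCell, Spatial, Visualization
Config/testthat/edition: 3
RoxygenNote: 7.3.3
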