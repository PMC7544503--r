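Package: cohesiontrack
Title: Tissue-Cohesion Analysis of 4D Embryonic Cell Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of lineage-resolved 4D nuclear tracking data from
    C. elegans embryos during head neuroectoderm involution. Provides
    readers for per-timepoint nuclei archives and flat track tables,
    Delaunay/Voronoi approximation of cell-cell contacts from nuclear
    positions, a contact-persistence screen for "interface" neurons that
    stay attached to the retracting pharynx, 3D velocity-correlation
    analysis of collective neuron motion, kinematic measurements
    (left-right convergence, pharynx retraction, net displacement, ROI
    fluorescence quantification), and a kinematic synthetic-embryo
    generator with ground truth for wild-type and adhesion-deficient
    (cadherin loss-of-function) conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
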