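Package: hexanematic
Title: Multiscale Hexatic and Nematic Shape Order in Epithelial Monolayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies p-atic (orientational) order of confluent epithelial
    monolayers across length scales. From junction-marker images or segmented
    cell polygons the package computes per-cell complex p-fold shape functions
    and the shape index, coarse-grains them into scale-dependent shape
    parameters on a square grid, locates the hexanematic crossover scale at
    which 6-fold (hexatic) order gives way to 2-fold (nematic) order, and
    detects topological defects of the coarse-grained orientation field via
    plaquette winding numbers. A synthetic-monolayer generator (Voronoi
    tessellations of perturbed triangular lattices, with rendered junction
    images) provides ground-truth data for validation, and a density-binning
    layer reproduces grouped summaries and rank-sum comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
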