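Package: cardiomesh
Title: Polygonal Surface Processing and Mesh Generation for Cardiac Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn unprocessed triangulated surfaces -- such as
    segmentations of heart chambers -- into tagged, analysis-ready surface
    and volume meshes.  Provides three algorithms to join separate surfaces
    (a greedy zipper between boundary rings, boolean connection of
    intersecting closed surfaces, and harmonic connection through a
    Laplace-Beltrami deformation), array-driven surface tagging, harmonic
    extension of point fields, wall-thickness computation and thickening,
    curvature- and thickness-driven mesh-size functions, tag-preserving
    isotropic remeshing, and volumetric operations: connection of
    tetrahedral meshes, sizing-driven refinement, and conversion of
    tetrahedral meshes to hexahedral ones.  Reads and writes STL, OBJ, PLY
    and VTK legacy ASCII files.  Deterministic synthetic generators of
    idealized cardiac geometries (shells, tubes, chambers) support fully
    reproducible pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
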