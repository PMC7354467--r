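Package: aortashape
Title: Statistical Shape Analysis of Ascending Aortic Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds a statistical shape atlas (mean template plus principal
    component shape modes) from populations of triangulated ascending-aorta
    surface meshes, computes clinically interpretable morphometric descriptors
    (station diameters, centerline tortuosity and curvature, dilatation-pattern
    class), estimates per-point systolic wall strain from paired
    diastole/systole meshes, and relates shape modes to descriptors and to the
    risk of aortic surgery via logistic models with ROC analysis. Includes a
    synthetic-aorta generator with known ground truth (shape-mode weights,
    strain fields, rigid perturbations, logistic surgery link) so that every
    pipeline stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    cluster,
    igraph,
    Matrix,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
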