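Package: osteomap
Title: Voxel-Based Compartment Mapping and Classification of Skull-Involving Meningiomas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic, atlas-space, voxel-based compartmentalization of
    skull-involving meningiomas (osteomeningiomas) from binary tumor and skull
    masks. Builds a mutually exclusive osseous / juxta-osseous("dural") /
    intradural compartment map from a skull mask using an exact anisotropic
    Euclidean distance transform, labels tumor voxels by compartment, and
    assigns the POM / SOM-I / SOM-IIA / SOM-IIB subtype from the per-compartment
    voxel counts, with multi-thickness sensitivity analysis. Includes seeded
    skull/lesion phantom generators with exact ground-truth compartment
    composition, cohort-level frequency maps and segmentation-agreement metrics,
    and the accompanying statistical layer (odds ratios with Woolf intervals,
    Fisher exact and Kruskal-Wallis tests, exploratory logistic regression with
    separation diagnostics).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
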