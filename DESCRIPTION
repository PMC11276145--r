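Package: condylometry
Title: Phantom-Validated Volumetric Morphometry of the Mandibular Condyle
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested reimplementation of a semiautomatic pipeline for
    measuring and comparing mandibular condylar head volume and surface
    from CBCT-like and MRI-like volumetric scans. Covers dual-polarity
    threshold segmentation with seeded selection and hole filling,
    iso-surface mesh extraction, rigid registration by Horn's absolute
    orientation plus iterative closest point refinement, landmark-defined
    two-plane condylar head isolation with watertight capping,
    surface/volume/cloud-distance morphometry, and replicate-agreement
    statistics (per-replicate deviation charts, Mann-Whitney,
    Kruskal-Wallis with Dunn-Bonferroni post hoc). A synthetic condyle
    phantom generator supplies ground-truth meshes and voxelized volumes
    so that every stage is verifiable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
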