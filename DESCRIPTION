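Package: cortexr
Title: High-Resolution Cortical MRI Processing and Equivolumetric Laminar Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing tools for high-resolution (submillimetre) structural
    brain MRI: MP2RAGE-oriented skull stripping, topology-preserving
    multi-object tissue segmentation with geometric deformable models,
    cortical boundary reconstruction by level-set evolution, signed-distance
    (level set) machinery with 3-D digital-topology control, and
    equivolumetric modeling of intracortical laminae. Includes a synthetic
    brain-phantom generator with known ground truth so the full pipeline can
    be exercised and validated without external data.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
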