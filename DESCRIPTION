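Package: condylomorph
Title: CT-Based Condylar Morphometry and Cohort Analysis for TMJ Disc Displacement Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify mandibular condyle bone modeling from surface
    meshes reconstructed from CT. Constructs a Frankfort-horizontal-parallel
    osteotomy plane through the sigmoid-notch point, separates and caps the
    condylar block, computes its volume by the divergence theorem, and builds
    seven anatomical surface landmarks (medial/lateral crest poles, apex, and
    anterior/posterior slope points on three section planes) with their
    heights above the osteotomy plane. Also computes cephalometric
    deformity/asymmetry indices (ANB, PN, ME), a rank-based and linear-model
    cohort statistical battery (quartile summaries, Mann-Whitney U with exact
    enumeration, pooled/Welch t-tests, two-way random absolute-agreement ICC,
    dummy-coded regression, noncentral-t sample-size calculation), and a
    synthetic condyle/cohort generator so every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tibble,
    dplyr,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
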