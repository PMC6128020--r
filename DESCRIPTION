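Package: vertefem
Title: Parametric Vertebral Segment Models and Distortion-Energy Response
    Analysis for Scoliosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Constructs artificial geometric models of scoliotic vertebral
    segments (the apex vertebra with its two neighbours and the two
    intervening discs) from a small per-vertebra parameter set: a conical
    frustum is wedge-cut in the coronal and sagittal planes and rigidly
    tilted, the segment is stacked and meshed with tetrahedra, and
    small-strain linear elasticity (isotropic or orthotropic bone, isotropic
    disc) is solved under a family of fifteen load-states built from a
    quadrant subdivision of the top face and optional lateral shear.  The
    distortion-energy density field on the apex top plane is summarised by a
    focus point and an apex top response angle relative to the sacrum line,
    and cohort-level statistics (per-load-state Pearson correlations with
    apex axial rotation and paired t-tests between model variants) are
    reported.  A seeded synthetic-cohort generator provides parameter sets
    with the structure of a right-convex thoracic scoliosis cohort so the
    full pipeline runs without patient imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
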