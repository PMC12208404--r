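Package: hipmorph
Title: Hip Shape Morphing and Musculoskeletal Gait Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for asking what happens when a modern
    human walks on an australopithecine-shaped hip. Provides parametric
    synthetic gait and hip-geometry generators, landmark-based bone
    morphing (thin-plate splines, rigid iterative-closest-point
    alignment, coherent point drift correspondence), rigid-segment
    inverse dynamics of walking, resolution of the muscle redundancy
    problem by minimising the sum of cubed activations, muscle-inclusive
    hip joint reaction forces, and one-dimensional statistical parametric
    mapping (permutation repeated-measures ANOVA) for comparing
    stride-normalised curves between hip shape variants under identical
    kinematics and kinetics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
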