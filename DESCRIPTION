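Package: ravgen
Title: Rule-Based Generation of Raven-Like Progressive Matrices
Version: 0.1.0
Authors@R: person("ravgen", "developers", role = c("aut", "cre"),
    email = "ravgen@example.org")
Description: Automatic generation of Raven-like progressive matrices for
    fluid-intelligence assessment. Provides a vector-figure model with a
    15-field feature record and a tag system, a transformation-rule engine
    (incremental, permutational, and logical AND/OR/XOR rules under
    horizontal, vertical, and diagonal directional logic), multi-layer
    matrix composition, and an automatic response-list generator producing
    the correct response plus ten theory-grounded distractors (repetition,
    wrong principle, difference, incomplete correlate). Matrices, figures,
    and response panels can be rendered to deterministic SVG or PNG, and a
    batch command-line workflow generates item banks from JSON
    configuration files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
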