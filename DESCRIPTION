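Package: skullfea
Title: Comparative Skull Feeding Biomechanics by Linear Tetrahedral Finite Elements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Linear elastostatic finite-element analysis on four-node
    tetrahedral meshes for comparative vertebrate feeding biomechanics.
    Provides STL and plain-text tetrahedral mesh input/output with named
    node sets, a parametric generator of skull-proxy meshes with jaw-joint
    constraints, bite-point loads and adductor muscle insertion patches,
    muscle-force estimation from adductor chamber cross-sectional area,
    surface-area-equalized load scaling to separate shape from size,
    mesh-weighted arithmetic mean (MWAM) von Mises stress and principal
    strain summaries, and a +/-10 percent muscle-force sensitivity
    analysis with symmetric percent-difference statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
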