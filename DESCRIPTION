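Package: bmpspec
Title: Structural Determinants of BMP9/BMP10 Specificity for ALK1
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural-informatics toolkit for dissecting how the BMP9/BMP10
    subfamily of bone morphogenetic proteins achieves its specificity for the
    endothelial type I receptor ALK1. Implements Shrake-Rupley solvent-accessible
    surface area and buried-interface analysis of two-group chain partitions,
    heavy-atom hydrogen-bond and salt-bridge detection with beta-sheet backbone
    ladder grouping, Kabsch rigid-body superposition with alignment-derived atom
    correspondence, a tripartite (family-conserved / subfamily-conserved /
    variable) conservation classifier mapped onto structure, beta-augmentation
    compatibility prediction for antagonist binding, interface swap-mutant
    design, and global fitting of 1:1 surface plasmon resonance kinetics with
    optional mass-transport limitation. Seeded synthetic-data generators provide
    oracle-checked fixtures for every analysis stage so the full pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
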