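Package: jacree
Title: Jouyban-Acree Cosolvency Modeling of Drug Solubility in Binary Solvent Mixtures
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modeling drug solubility in binary solvent mixtures with
    the Jouyban-Acree log-linear cosolvency model. Converts saturation data
    between nine solute/solvent concentration-unit combinations (mole fraction,
    molar and gram-per-liter solute units crossed with mole, mass and volume
    solvent-composition bases), estimates the model's interaction (J)
    coefficients by ordinary least squares with optional significance-based
    backward elimination, back-calculates solubilities, evaluates five error
    criteria (MRD%, arithmetic and logarithmic RMSD, arithmetic and logarithmic
    mean absolute error), and orchestrates comparative multi-code studies,
    composition-skew diagnostics and outlier-perturbation experiments. A
    synthetic-data generator with van't Hoff temperature anchors and a
    configurable saturated-solution density model provides ground truth for
    every analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
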