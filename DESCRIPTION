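Package: ilpc
Title: Qualitative Physicochemical Screening of Ionic Liquids from
    Constitutional Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the 41-member constitutional (0D) descriptor block for
    the cation and the anion of an ionic liquid directly from SMILES, places
    the salt on a fixed two-principal-component chemical-space map fitted to a
    reference set, assigns it to one of six structural clusters by Ward
    hierarchical clustering, and returns qualitative predictions (low, medium,
    high) for viscosity, n-octanol-water partition coefficient, aqueous
    solubility and enthalpy of fusion from documented trend rules on the
    component scores. Also provides a QSPR workflow for quantitative
    enthalpy-of-fusion modelling: rank-based training/validation split,
    genetic-algorithm descriptor selection, multiple linear regression with
    leave-one-out and external validation statistics, and a leverage-based
    applicability domain. A deterministic synthetic reference-set generator
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
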