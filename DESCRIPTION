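Package: epimapr
Title: Epitope Mapping from Ortholog Panels, Peptide Tiling, Flow Binding
    and Antibody-Antigen Interface Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for localizing the binding epitope of an antibody on a
    cell-surface antigen. Designs species chimeras and surface patch mutants
    from differential conservation across labelled ortholog panels, localizes
    epitopes from overlapping tiling-peptide binding arrays, normalizes
    flow-cytometry binding to display level with permutation-based
    many-to-one testing, and quantifies the antibody-antigen interface from
    atomic coordinates (solvent-accessible and buried surface area, contacts,
    hydrogen bonds, disulfides, relative accessibility, Kabsch superposition,
    substitution-impact scanning). Includes seeded synthetic-data generators
    with analytic oracles so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    jsonlite,
    withr,
    generics,
    stats,
    utils,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
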