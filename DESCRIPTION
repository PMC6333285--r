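Package: sf4kit
Title: Geometry, Restraints and Validation for Fe4S4 Iron-Sulfur Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the cubane-type Fe4S4 iron-sulfur cluster (PDB
    chemical component 'SF4'): construction of ideal rhomboid and cubic
    coordinate templates from restraint targets, generation and
    reading/writing of monomer-library style restraint dictionaries
    (component and SF4-CYS link), symmetry-aware canonicalization of
    cluster atom names by least-squares superposition over the proper
    relabelings of the cubane graph, automatic detection of
    iron-to-cysteine coordination links, restraint-RMSD validation and
    classification of observed clusters, geometry-statistics mining of
    structure corpora under resolution/R-factor/completeness filters, and
    a seeded synthetic-structure generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    broom,
    dplyr,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
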