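Package: mgion
Title: Stereochemical Validation and Classification of Mg2+ and K+
    Binding Sites in Nucleic Acid Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies, validates and classifies Mg2+ (and paired K+)
    binding sites in nucleic-acid and protein three-dimensional
    structures.  Reads mmCIF/PDB coordinate files into a typed atom
    table, assigns each oxygen/nitrogen a chemical-role category,
    builds first coordination shells around metals, scores octahedral
    distortion, names every hexacoordinated site with the extended
    MgRNA nomenclature (cis-/trans-/fac-/mer-/Cis-/Trans- isomer
    prefixes), screens structures for bidentate phosphate clamps via
    the short OP...OP distance rule, detects head-to-tail stacked
    purine N7 seats and O2'-phosphate motifs, and classifies Mg...Mg
    and Mg...K ion pairs into a micro-cluster taxonomy.  Ships a
    deterministic synthetic-fixture generator so the whole pipeline is
    testable without downloading structures, plus a small command-line
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
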