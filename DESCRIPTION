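Package: psnmut
Title: Structure-Network Assessment of Cancer Missense Mutations from
    Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links cancer missense mutations to the structural ensemble of a
    protein kinase domain. Builds persistence-weighted protein structure
    networks (contacts, salt bridges, hydrogen bonds) from multi-model PDB
    ensembles, finds hub residues and shortest communication paths to
    functional residue classes, compares essential subspaces of two ensembles
    by principal component analysis and RMSIP, aggregates saturation
    mutagenesis free-energy scans, curates mutation tables with REVEL, PTM and
    short-linear-motif annotations, tests mutation co-occurrence, and combines
    every descriptor into per-mutation stability (0-2) and function (0-5)
    damaging scores.
License: MIT
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
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
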