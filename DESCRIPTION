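Package: reepitope
Title: Antibody Re-Epitoping Toolkit: Interface Analysis, Focused Library
    Design, and Epitope Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational toolkit for antibody re-epitoping: redirecting a
    mature template antibody to a new, unrelated antigen with a minimal
    number of mutations. Provides structure handling (PDB/mmCIF), contact and
    paratope/epitope analysis at a 5 Angstrom heavy-atom cutoff, buried
    surface area by Shrake-Rupley sampling, a Lawrence-Colman-style shape
    complementarity statistic, cross-complex paratope conservation
    accounting, IMGT numbering and germline V-gene assignment by
    alignment transfer, focused combinatorial library specification with
    exact size and identity statistics, random-forest classifiers for
    docking-pose discrimination (interface features over rigid-body decoys)
    and for antibody-position by antigen-residue pair scoring with grouped
    cross-validation, spatial aggregation propensity (SAP) surface scoring,
    and deterministic synthetic-fixture generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
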