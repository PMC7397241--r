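Package: kinasespace
Title: Chemical Space, Scaffold and Ring-System Diversity Analysis of
    Kinase Inhibitor Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for profiling the chemical space of protein kinase
    inhibitor (PKI) libraries. Reads and standardizes molecule sets
    (SMILES, SDF, CSV), computes a twelve-descriptor physicochemical
    panel with Lipinski/Veber rule profiling and mean +/- 2 SD design
    guidelines, performs correlation-metric PCA with variable
    contributions and 95% class ellipses, generates seeded conformers
    for principal-moments-of-inertia (PMI) shape analysis, decomposes
    molecules into Bemis-Murcko scaffolds and graph frameworks with
    diversity statistics, classifies fused ring-system ensembles in
    unpositioned and positioned (typed attachment point) encodings,
    computes fingerprint similarity statistics with Butina clustering,
    and builds bioactivity-filtered comparison sets. A seeded synthetic
    library generator with planted ground truth makes every stage
    testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    igraph,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: OpenBabel 3 (obabel on PATH), Python 3 with RDKit
    (seeded conformer embedding)
Config/testthat/edition: 3
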