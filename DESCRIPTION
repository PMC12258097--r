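Package: evoscape
Title: Scale-Explicit Phylogenetic Uniqueness, Endemism and
    Conservation Prioritisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for scale-explicit analysis of phylogenetic uniqueness
    across site networks. Implements the asymmetric Ruggiero phylogenetic
    dissimilarity (the proportion of a focal community's branch length not
    shared with a comparison community), per-site negative-exponential
    distance-increase models of that dissimilarity against geodesic
    distance, Rosauer phylogenetic endemism, Faith's PD accumulation
    curves under alternative prioritisation criteria, and a quartile-based
    classification of high-endemism sites into evolutionary hills and
    evolutionary islands. Includes synthetic landscape generators with
    planted isolation structure for validation, file readers and writers
    for trees, community matrices and site coordinates, and a subcommand
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    picante,
    minpack.lm,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
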