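Package: pocketrepo
Title: Binding-Pocket Matching, Pose Transfer and Statistical Scoring for
    Drug Repositioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares drug-binding pockets by sequence-order-independent
    alignment solved as an optimal assignment problem, corroborates matches
    with virtual-screening rank correlation, transfers drug poses between
    matched pockets with rigid-body clash relief, and scores the resulting
    complexes with a distance-scaled finite ideal-gas reference statistical
    potential. Includes BEDROC early-recognition evaluation, molecular
    descriptors (molecular weight, Ertl topological polar surface area,
    Crippen logP, path fingerprints, maximum common substructure), and a
    deterministic synthetic-fixture generator so the full repositioning
    pipeline runs end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    bio3d,
    ChemmineR,
    ChemmineOB,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
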