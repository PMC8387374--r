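Package: tumorgeo
Title: Phylogenetic Biogeography of Tumor Clone Migrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs metastatic cell migration histories by treating tumor
    sites as biogeographic areas and clone phylogenies as species trees. Fits
    the dispersal-extinction-cladogenesis family of ancestral-range models
    (BAYAREALIKE, DEC, DIVALIKE, each with or without founder-event jump
    dispersal) to a rooted clone tree with per-clone tumor-site labels by
    maximum likelihood, compares models with likelihood-ratio tests and
    AICc/BIC, annotates ancestral nodes with their highest-probability range,
    derives directed site-to-site migration paths from annotation changes along
    tree edges, and scores inferred migration graphs against a known truth with
    precision, recall and F1. Includes a seeding-scenario simulator
    (monoclonal/polyclonal, single/multi-source, with reseeding) that generates
    clone trees, infinite-sites genotypes and true migration graphs for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    withr,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
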