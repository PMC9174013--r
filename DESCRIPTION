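Package: cernet
Title: Competing Endogenous RNA Network Inference from Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers circRNA-miRNA-mRNA competing endogenous RNA (ceRNA)
    networks from tumor versus matched-normal expression profiles.
    Provides empirical-Bayes moderated t-tests for differential
    expression with Benjamini-Hochberg adjustment, sign-consistent
    cross-dataset intersection of calls, multi-database consensus
    filtering of miRNA target catalogs, direction-consistent triad
    assembly under the two ceRNA regulation paradigms, hypergeometric
    over-representation analysis, protein-protein interaction hub-gene
    extraction by degree, and relative quantification of qPCR
    validation data by the 2^-ddCt method. A seeded synthetic-study
    generator with planted ground truth supports end-to-end recovery
    testing without external database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
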