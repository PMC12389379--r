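Package: mirbiblio
Title: Bibliometric Mining of microRNA Literature Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for bibliometric analysis of microRNA-focused literature
    corpora exported from citation databases. Parses Scopus-style CSV exports
    into tidy corpora, applies relevance screening, extracts and validates
    miRNA identifiers against multi-release miRBase-style nomenclature
    catalogs, computes publication and citation indicators (annual production,
    geometric growth rate, global and local citation scores, citations per
    year), attributes articles to countries (author appearances,
    single-country and multiple-country publications), builds keyword
    co-occurrence and country collaboration networks with association-strength
    normalization and community detection, and generates seeded synthetic
    corpora with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
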