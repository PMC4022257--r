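Package: seapattern
Title: Microbe-Environment Association Patterns from Amplicon Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines association patterns between microbial taxa and
    environmental factors from amplicon sequence surveys. Provides
    homopolymer-aware greedy OTU clustering with neighbor seeds, relative
    abundance filtering and normalization, binned mutual-information
    association networks with permutation-test edge significance, symmetric
    nonnegative matrix factorization for fuzzy community detection with
    modularity-based model selection, network topology reports against
    random-graph references, and seeded synthetic-data generators for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
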