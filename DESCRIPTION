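Package: labordiv
Title: Evolution of Mechanisms to Divide Labor in Microbial Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical and individual-based models of reproductive division of
    labor in social microbes whose groups are founded by one or more lineages
    (within-group relatedness 1/l). The analytical layer computes expected
    fitness of fully random and fully coordinated specializers, evolutionarily
    stable target helper proportions, pairwise invasion conditions between the
    two mechanisms, and phase diagrams over the essentiality of cooperation and
    group size. The simulation layer is an individual-based model in which the
    target helper proportion and a continuous level of between-cell
    coordination coevolve under a haystack life cycle with global competition
    and mutation, with a compiled inner loop for speed. Results are returned as
    tibbles with broom-style tidiers and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
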