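Package: mvnet
Title: Multi-State Logical Network Models with Exhaustive Attractor Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build, validate, and analyze multi-valued logical models of
    regulatory networks (generalized Boolean networks in which each node takes
    2-5 ordinal states). Transition tables are auto-generated by an additive
    rule with clamping and can be overridden row by row. The synchronous state
    space is enumerated exhaustively to find all attractors (steady states and
    limit cycles) with their basins of attraction, and nodes can be pinned to
    constant states to simulate knockout, knockdown, and overexpression
    experiments. Models round-trip through a versioned JSON format; results
    export to CSV, DOT, and GraphML.
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
    optparse,
    purrr,
    readr,
    rlang,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
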