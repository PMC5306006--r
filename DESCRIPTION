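Package: nestflow
Title: Dynamic Nest-Network Analysis of Polydomous Ant Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the dynamics of polydomous ant colonies
    mapped as spatially embedded nest-and-tree networks. Builds weighted
    colony maps from field node/edge tables, computes resource-flow
    (weighted, normalised betweenness) and colony-level metrics, links nest
    identities across repeated blind mappings, extracts abandonment and
    budding events, and tests survival and founding effects with an
    extended Cox proportional-hazards framework whose significance comes
    from a quadratic assignment procedure (QAP) permutation null
    constrained within each colony map, plus binomial mixed models with
    chi-squared analysis of deviance. Includes a synthetic colony
    simulator with known ground truth for calibration and power studies.
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
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
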