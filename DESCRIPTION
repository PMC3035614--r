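Package: nichestates
Title: Alternative Stable States in Stage-Structured Consumer-Resource Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing alternative stable states (ASS) generated by
    an ontogenetic niche shift in stage-structured consumer-resource systems
    with multiple resource use. Implements three model scenarios (additional
    resources per stage, multiple habitats per stage, and interstage resource
    sharing), zero-net-growth-isocline (ZNGI) analysis, reduction of the
    coexistence equilibria to a cubic polynomial with a discriminant-based
    bistability condition, Jacobian stability classification, numerical
    integration with attractor detection and counting across initial
    conditions, and boolean ASS maps over two-parameter planes, including an
    allochthonous-subsidy variant and a heterogeneous-habitat multistability
    search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
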