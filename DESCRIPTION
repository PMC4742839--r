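Package: hepaflux
Title: Genome-Scale Metabolic Assessment of Liver Functionality from
    Expression and Splanchnic Flux Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constraint-based analysis of liver metabolic functionality.
    Integrates gene-expression profiles and measured splanchnic exchange
    fluxes with a genome-scale metabolic model to score the activity and
    adaptability of key liver metabolic functions (gluconeogenesis,
    ureagenesis, ketogenesis and others), using iMAT-style mixed-integer
    expression integration, quadratic-programming flux fitting, flux
    variability analysis, pathway enrichment, permutation statistics and
    SVM classification of liver-fat phenotypes. Ships a synthetic-data
    generator (toy stoichiometric networks, two-group expression cohorts
    with planted effects, noisy flux measurements) so the full pipeline is
    testable without cohort downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    xml2,
    reticulate,
    quadprog,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
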