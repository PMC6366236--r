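Package: coopassort
Title: Cooperative Phenotypes and Social Assortment in Animal Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing cooperative phenotypes and their link to
    social structure in wild animal populations, motivated by predator
    inspection in Trinidadian guppies. Implements one-way ANOVA
    repeatability of repeated cooperativeness scores with Monte-Carlo
    permutation p-values and false-discovery-rate control; simple ratio
    index (SRI) association networks from group-by-individual shoal
    observations with a minimum-sightings filter; data-stream and
    edge-weight permutation null models; weighted and unweighted
    assortativity coefficients for continuous and categorical node traits
    with two-tailed permutation tests; dyadic correlation tests of edge
    weight against summed cooperativeness and pairwise relatedness; and a
    synthetic-data generator with known ground truth (variance components,
    tunable trait assortment, block kin structure) so every stage can be
    validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
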