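Package: vocsignal
Title: Phylogenetic Signal and Developmental Constraints in Fruit Volatile Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing volatile organic compound (VOC) tables from
    fruit headspace sampling: compound filtering and normalization, aggregation
    into biochemical classes, Bray-Curtis dissimilarities and principal
    coordinates, multivariate phylogenetic signal (Blomberg's K and its
    multivariate extension Kmult) with permutation inference on a phylogeny,
    and ripe-versus-unripe class-composition correlation analysis. Includes a
    synthetic-data generator (Yule trees, Brownian-motion traits, zero-inflated
    compositional scent tables, copula-paired ripe/unripe profiles) so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    picante,
    phytools,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
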