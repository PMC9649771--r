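Package: traitstack
Title: Stacked Trait-Decile Distribution Models for Mapping Genetically
    Based Trait Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping how climate constrains genetically based
    functional trait variation across a species' range. Genotype trait
    measurements (spring leaf-out day of year from a common garden) are
    partitioned into trait deciles, a presence-background
    maximum-entropy-style distribution model is fitted per decile against
    environmental raster layers, binarized with a training-presence
    threshold, and the binary maps are stacked into per-cell trait
    ("decile") richness. Current and future climate scenarios are compared
    as richness-change maps, net loss summaries, trait-distribution
    similarity scores over decile-combination community matrices, and
    constrained ordination (redundancy analysis) with permutation tests.
    Includes a seeded synthetic-landscape generator (environmental
    gradients, a dendritic stream network, and population-structured
    genotypes) so the whole pipeline can be exercised and validated
    without proprietary occurrence or climate data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
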