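Package: traitmatch
Title: Partitioning Plastic, Genetic and Species-Turnover Contributions to
    Trait-Environment Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how plant trait-environment matching
    arises along environmental gradients. Partitions intraspecific trait
    variation from reciprocal transplant experiments into plastic (E),
    genetic (G) and GxE components via type III sums of squares and the
    percent-E plasticity share; decomposes community-weighted-mean trait
    turnover along a gradient into species-turnover, intraspecific and
    covariation components; and estimates within-site Lande-Arnold
    selection differentials and gradients to test whether selection points
    toward the community-weighted mean. Includes a synthetic-data module
    that reproduces the statistical structure of a two-transect,
    three-elevation reciprocal transplant so that every analysis stage can
    be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    emmeans,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    withr
Config/testthat/edition: 3
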