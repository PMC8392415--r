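Package: sensorep
Title: Word-Association and Free-Sorting Analysis of Consumer Product Representations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying how consumer groups mentally represent a food
    product, built around two classic sensometric tasks. For free
    word-association data it computes corpus diversity and rarity indices,
    semantic category frequency tables with chi-square comparisons and
    one-way ANOVAs on importance and valence ratings, and the prototypical
    (central-core) analysis that partitions evoked words into a central core
    and three peripheral zones from frequency and importance cut-offs. For
    free-sorting data it encodes individual partitions as 0/1 distance
    matrices and runs DISTATIS: normalized cross-products, RV coefficient
    matrix, weighted compromise, factor and partial factor scores, bootstrap
    confidence regions, and supplementary projection of group descriptors
    and origin barycentres. A hypergeometric specificity test flags
    descriptors over-represented in one experimental condition. Seeded
    synthetic panel generators emulate cross-cultural study designs so the
    whole pipeline can be exercised without proprietary consumer data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
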