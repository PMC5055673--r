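Package: phylospot
Title: Spatial Hotspots of Threatened and Range-Restricted Evolutionary History
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies grid cells that concentrate threatened and range-restricted
    evolutionary history from a dated phylogeny, a cells-by-species occurrence
    matrix, IUCN threat categories and protected-area coverage. Implements
    expected phylogenetic diversity loss under independent species extinctions,
    heightened evolutionary distinctiveness and global endangerment (HEDGE), and
    biogeographically weighted evolutionary distinctiveness (BED); screens cells
    with two permutation null models (risk shuffles across the phylogeny and
    identity shuffles within cells at fixed richness); selects hotspots under the
    Aichi 17% rule or threshold-based alternatives; and evaluates protected-area
    coverage of hotspots under minimum and strong protection scenarios with a
    randomization test. A synthetic-data module (Yule trees, spreading-dye
    ranges, phylogenetically clustered threat categories, protection layers)
    makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
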