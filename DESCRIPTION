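Package: endophylo
Title: Gene-Tree Discordance, Topology Scenarios, and Genome-Trait
    Evolution in Orchids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Dissects gene-tree/species-tree discordance with per-node
    concordance accounting, a taxon-removal jackknife, and a
    clade-representative alternative-topology scenario test; derives
    genome size, partial-endoreplication fraction, and GC content from
    flow-cytometry peak tables; reconstructs pseudo-occurrence ranges
    from botanical regions and elevation bands to build area-weighted
    trait surfaces; and fits phylogenetic comparative models (Pagel's
    lambda, PGLS with predictor uncertainty, phylogenetic ANOVA,
    independent contrasts, ancestral states, and branch-wise
    significant-change detection). A synthetic-data module simulates
    multispecies-coalescent gene trees, hybrid topology signal,
    Brownian traits, flow-cytometry peak series, and landscapes so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    phytools,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
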