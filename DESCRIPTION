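Package: hotspotTF
Title: Predicting Trans-Acting Regulators of Recombination Hotspots from
    Binding-Site Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for screening DNA-binding proteins for a regulatory role at
    meiotic recombination hotspots. Hotspot intervals and length-matched,
    distance-constrained coldspot controls are scanned with a position-weight-
    matrix scanner whose exact score p-values are computed by dynamic
    programming; per-region hit indicators feed a hotspot/coldspot odds ratio
    with Yates-corrected chi-square significance, averaged over replicate
    coldspot draws. Candidate regulators are characterised by a Gene Ontology
    semantic-similarity gap statistic (Wang-style graph similarity) and by
    clustering of a meet/min hotspot-coverage graph. A synthetic-data module
    generates genomes, hotspots, planted motifs and a toy ontology with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    igraph,
    methods,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
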