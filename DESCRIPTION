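Package: ccrelink
Title: TAD-Constrained cCRE-Gene Linking and Selector TF Evidence Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream regulatory-genomics analyses for single-cell multiome
    studies of neuronal lineage bifurcation: feature-to-gene linkage z-scores
    restricted to topologically associating domains (TADs), conservation-weighted
    scoring of transcription factor binding sites, three-evidence regulator
    identification with a permutation null for multi-set overlaps, four-evidence
    (footprint, linkage, conservation, CUT&Tag) target-gene calling and
    characterization, footprint/peak corroboration statistics, cross-modality
    cluster marker matching, and apical-basal image-profile quantification.
    Includes a synthetic multiome generator with planted regulatory ground
    truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tools,
    Matrix,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
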