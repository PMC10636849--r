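Package: skincat
Title: Skin Microbiome Genome Catalog Construction and Mother-Infant Sharing Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision logic for building a metagenome-assembled genome (MAG)
    catalog of the early-life skin microbiome and for the downstream
    multi-level mother-infant microbial-sharing analyses. Consumes abstracted
    upstream-tool outputs (genome quality metrics, pairwise ANI edge lists,
    species abundance tables, SNV call tables, MLST allele profiles, gene
    presence/absence matrices) and provides MIMAG-style quality tiering,
    two-stage ANI dereplication and species clustering with scored
    representatives, rarefaction and classification-improvement statistics,
    community diversity and dyad comparisons, pan-genome core/accessory
    functional enrichment, conspecific SNV density, and a sequence-type
    sharing permutation test. A synthetic-data generator with ground-truth
    labels makes the whole pipeline testable end-to-end without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    vegan,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
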