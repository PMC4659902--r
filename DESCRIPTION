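Package: otucoherence
Title: Ecological Coherence of Bacterial Classes and Their Constituent
    OTUs Along a Regulated River
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify how faithfully abundance patterns of
    high-rank bacterial classes represent the dynamics of their
    constituent operational taxonomic units (OTUs) along a dam-regulated
    river. Provides validated OTU-table, taxonomy, tree, metadata and
    environmental-table input/output; rarefaction and alpha diversity
    (richness, Shannon, mean pairwise phylogenetic distance); Bray-Curtis
    and weighted-normalized UniFrac distances with ANOSIM contrasts
    between river reaches and sampling campaigns; OTU origin and
    reach-dominance categorization under unidirectional flow; a per-class
    partition of OTUs by the sign and significance of their correlation
    with parent-class abundance, with subgroup diversity summaries;
    oblimin-rotated principal component analysis of environmental
    variables and OTU/class correlations with the rotated axes; and a
    synthetic river-metacommunity generator with planted, exported ground
    truth so every stage can be validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    ape,
    picante,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    biomformat,
    jsonlite,
    phyloseq,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
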