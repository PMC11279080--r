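Package: poolnet
Title: Spatial and Seasonal Microbial Community Analysis for Wetland
    Breeding Pools
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for spatial and seasonal structure of
    bacterial, fungal and protist communities in montane wetland
    amphibian breeding pools, from amplicon sequence variant (ASV)
    count tables. Implements rarefaction, non-target taxon filtering,
    Chao1 and Shannon-Wiener alpha diversity with ANOVA/Tukey group
    comparisons, Bray-Curtis NMDS ordination, PCA of water chemistry,
    Mantel tests linking water properties to community dissimilarity,
    Pearson screens between chemistry and taxon abundances, and
    per-site co-occurrence networks (Spearman correlation with
    Benjamini-Hochberg FDR thresholding) with module detection,
    topological summaries and Zi-Pi keystone role classification. A
    seeded synthetic-community generator reproduces the 8-site by
    11-month study design with planted spatial, seasonal and guild
    structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    mclust,
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
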