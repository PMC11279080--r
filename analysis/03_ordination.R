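#!/usr/bin/env Rscript
# Step 3 — ordination.
#
# Bray-Curtis NMDS of the bacterial community (spatial structure should
# dominate: core pools separate from edge pools) and PCA of the nine
# water-chemistry variables with per-variable contributions.

library(poolnet)

SEED <- 2024L
md <- read.delim("results/data/metadata.tsv", stringsAsFactors = FALSE)
chem <- read.delim("results/data/chemistry.tsv", stringsAsFactors = FALSE)
c16 <- read_count_table("results/data/asv_16s.tsv")
r16 <- rarefy(c16, min(rowSums(c16)), seed = derive_seed(SEED, "r16"))

bc <- bray_curtis(r16)
fit <- nmds(bc, k = 2, n_starts = 20, seed = derive_seed(SEED, "nmds"))
coords <- data.frame(sample_id = rownames(fit$points), fit$points)
coords <- merge(coords, md, by = "sample_id", sort = FALSE)
write.table(coords, "results/nmds_bacteria.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("NMDS (k = 2): stress = %.3f over %d samples", fit$stress,
                nrow(fit$points)))
sep <- tapply(coords$MDS1, coords$zone, mean)
message(sprintf("mean NMDS1: core %+.3f vs edge %+.3f", sep["core"], sep["edge"]))

pca <- chem_pca(chem)
write.table(data.frame(variable = rownames(pca$contributions), pca$contributions),
            "results/pca_contributions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("chemistry PCA: PC1 %.1f%%, PC2 %.1f%% of variance",
                100 * pca$explained_variance[1], 100 * pca$explained_variance[2]))
top <- sort(pca$contributions[, 1], decreasing = TRUE)[1:3]
message(sprintf("top PC1 contributors: %s",
                paste(sprintf("%s (%.0f%%)", names(top), top), collapse = ", ")))
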