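#!/usr/bin/env Rscript
# Step 4 — water chemistry vs community structure.
#
# Mantel tests (9999 permutations) between each community's Bray-Curtis
# matrix and Euclidean distance on each z-scored chemistry variable, plus
# the per-cell Pearson screen between chemistry and phylum relative
# abundances. Planted links: Cyanobacteria anti-correlated and
# Actinobacteria correlated with temperature; Alveolata with TP.

library(poolnet)

SEED <- 2024L
md <- read.delim("results/data/metadata.tsv", stringsAsFactors = FALSE)
chem <- read.delim("results/data/chemistry.tsv", stringsAsFactors = FALSE)
tax <- read_taxonomy("results/data/taxonomy.tsv")
c16 <- read_count_table("results/data/asv_16s.tsv")
c18 <- read_count_table("results/data/asv_18s.tsv")
r16 <- rarefy(c16, min(rowSums(c16)), seed = derive_seed(SEED, "r16"))
r18 <- filter_nontarget_protists(
  rarefy(c18, min(rowSums(c18)), seed = derive_seed(SEED, "r18")), tax)

grp <- setNames(tax$group, tax$taxon_id)
tables <- list(bacteria = r16,
               fungi = count_table(unclass(r18)[, grp[colnames(r18)] == "fungi", drop = FALSE]),
               protist = count_table(unclass(r18)[, grp[colnames(r18)] == "protist", drop = FALSE]))
dists <- lapply(tables, bray_curtis)

mt <- mantel_table(dists, chem, n_permutations = 9999,
                   seed = derive_seed(SEED, "mantel"))
write.table(mt, "results/mantel_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
tm <- mt[mt$property == "Temp", ]
message(sprintf("Mantel vs temperature: bacteria R = %.3f (p = %.4g), fungi R = %.3f, protist R = %.3f",
                tm$bacteria_R, tm$bacteria_p, tm$fungi_R, tm$protist_R))

ra <- do.call(cbind, lapply(names(tables), function(g)
  aggregate_relative_abundance(tables[[g]], tax, "phylum")))
scr <- pearson_screen(chem, ra)
out <- data.frame(variable = rep(rownames(scr$r), ncol(scr$r)),
                  taxon = rep(colnames(scr$r), each = nrow(scr$r)),
                  r = as.vector(scr$r), p = as.vector(scr$p),
                  significant = as.vector(scr$significant))
write.table(out, "results/pearson_screen_phylum.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("Pearson screen: %d of %d cells significant at p < 0.05",
                sum(scr$significant), length(scr$significant)))
for (t in c("Cyanobacteria", "Actinobacteria")) {
  message(sprintf("  Temp vs %-15s r = %+.3f (p = %.2g)", t,
                  scr$r["Temp", t], scr$p["Temp", t]))
}
message(sprintf("  TP   vs %-15s r = %+.3f (p = %.2g)", "Alveolata",
                scr$r["TP", "Alveolata"], scr$p["TP", "Alveolata"]))
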