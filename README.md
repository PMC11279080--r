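# poolnet

Spatial and seasonal analysis of microbial communities in wetland
amphibian breeding pools: alpha diversity, ordination, water-chemistry
association tests, and per-site co-occurrence networks with keystone
(Zi–Pi) classification.

## What it is for

Surveys of small montane breeding pools typically produce, per marker gene
(16S for bacteria, 18S for fungi and protists), a sample-by-ASV count
table over a sites × months design, together with per-sample water
chemistry (pH, temperature, DO, EC, turbidity, TN, TP, COD~Mn~, Chl *a*).
`poolnet` is for ecologists who want the standard downstream chain over
such tables, reproducibly and with every step testable:

- **Alpha diversity** — Chao1 `S_obs + F1(F1−1)/(2(F2+1))` and
  Shannon–Wiener `H' = −Σ p_i ln p_i` on rarefied counts, with one-way
  ANOVA + Tukey HSD letters across sites and months.
- **Ordination** — Bray–Curtis `d_ij = Σ|x_ik − x_jk| / Σ(x_ik + x_jk)`
  with NMDS (Kruskal stress-1, best of 20 starts), and PCA of z-scored
  chemistry with per-variable contributions.
- **Association** — Mantel tests (9999 permutations, one-sided) between
  community dissimilarity and Euclidean distance on z-scored chemistry,
  plus a per-cell Pearson screen between chemistry and phylum/genus
  relative abundances.
- **Co-occurrence networks** — per site, across the 11 monthly samples of
  the pooled three-kingdom table: prevalence/abundance filter (≥ 7
  months, ≥ 12 reads), all-pairs Spearman correlation, Benjamini–Hochberg
  FDR, edges at |ρ| > 0.7 and adjusted p < 0.01, Louvain modules,
  topological summaries (degree, modularity Q, betweenness, closeness,
  clustering, path distance), and node roles from within-module
  connectivity Zi and among-module connectivity `Pi = 1 − Σ (k_is/k_i)²`
  (network hub Zi > 2.5 & Pi > 0.62; module hub Zi > 2.5; connector
  Pi > 0.62; peripheral otherwise).

A seeded synthetic-community generator reproduces the 8-site × 11-month
design (88 samples, no February) with planted core/edge diversity
gradient, seasonal temperature forcing, eutrophication covariates,
chemistry-linked taxa and co-occurring ASV guilds — with a ground-truth
record, so every stage's recovery can be scored.

## Worked example

The `analysis/` scripts run the whole study on a simulated bundle and
narrate what they find. `Rscript analysis/01_simulate.R` writes the input
tables under `results/data/`; the later steps print, for example:

```
$ Rscript analysis/02_alpha_diversity.R
rarefied to 49470 (16S) and 49469 (18S) reads/sample; removed 12 non-target 18S ASVs
bacteria: Shannon edge - core = +0.408; site ANOVA F = 2.72, p = 0.0138
fungi: Shannon edge - core = +0.366; site ANOVA F = 51.76, p = 4.11e-27
protist: Shannon edge - core = +0.319; site ANOVA F = 24.95, p = 1.05e-17
```

Positive edge-minus-core gaps recover the planted pattern: the eutrophic
core pools (Site 3–5) are less diverse than the edge pools.

```
$ Rscript analysis/04_chemistry_associations.R
Mantel vs temperature: bacteria R = 0.267 (p = 0.0001), fungi R = 0.105, protist R = 0.130
Pearson screen: 39 of 135 cells significant at p < 0.05
  Temp vs Cyanobacteria   r = -0.727 (p = 1.1e-15)
  Temp vs Actinobacteria  r = +0.681 (p = 2.9e-13)
  TP   vs Alveolata       r = +0.837 (p = 3.3e-24)
```

The three planted chemistry–taxon links come back with their planted
signs. Finally the network stage:

```
$ Rscript analysis/05_networks.R
Inlet   146 nodes   461 edges (99.6%+) Q = 0.757 | guild sensitivity 1.00, ARI 1.00 | 1 hubs, 1 connectors
Site1   122 nodes   266 edges (97.4%+) Q = 0.831 | guild sensitivity 0.80, ARI 1.00 | 0 hubs, 0 connectors
...
Outlet  128 nodes   289 edges (96.2%+) Q = 0.832 | guild sensitivity 1.00, ARI 1.00 | 1 hubs, 0 connectors
```

Guild sensitivity is the fraction of planted within-guild pairs recovered
as network edges; ARI compares detected modules with the planted guild
labels (1 = perfect). Per-site GraphML files carry node attributes
(module, degree, Zi, Pi, role, taxonomy) and signed edges for any graph
tool.

The same chain is available as one call:

```r
library(poolnet)
report <- run_pipeline(pipeline_config(scenario = scenario_config(seed = 1),
                                       output_dir = "results/run1", seed = 1))
```

which writes every table, network and a reconciled JSON run report, fully
deterministic under the seed.

## Methods

See `vignettes/poolnet-methods.Rmd` for the statistical model of each
stage, the generator's design, and the numerical decisions (threshold
order, boundary semantics, degenerate-input conventions).
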