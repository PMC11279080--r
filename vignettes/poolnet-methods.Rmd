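---
title: "Methods: spatial-seasonal microbial community analysis for wetland breeding pools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial-seasonal microbial community analysis for wetland breeding pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`poolnet` implements a complete analysis chain for spatially and seasonally
structured aquatic microbial communities, built around the survey design of
montane wetland amphibian breeding pools: eight sampling stations (a water
inlet, six breeding pools, an outlet) sampled monthly over a year with
February suspended, giving 88 samples per marker gene (16S for bacteria, 18S
for fungi and protists). This vignette documents the statistical model of
each stage, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the numerical decisions taken where
the design was genuinely open.

## The analysis chain

1. **Rarefaction.** Each sample is subsampled without replacement
   (hypergeometric) to a common depth. For real tables the defaults are
   44,465 (16S) and 39,865 (18S) reads per sample; for simulated tables the
   depth is the minimum sample total, mirroring the convention of rarefying
   at the minimum number of sequences per sample. Samples below depth are
   dropped and logged.
2. **Non-target filtering (18S).** ASVs whose lineage contains Metazoa,
   Opisthokonta, Rhodophyta or Streptophyta — multicellular, plant and
   red-algal amplicons that broad eukaryotic primers co-amplify — are
   removed, as are ASVs unassigned at the configured rank (default phylum).
3. **Alpha diversity.** Chao1 (bias-corrected,
   $S_{obs} + F_1(F_1-1)/(2(F_2+1))$) and Shannon–Wiener
   ($H' = -\sum p_i \ln p_i$, natural log). Sites and months are compared by
   one-way ANOVA with all-pairs Tukey HSD (Tukey–Kramer on unbalanced
   designs) and an insert–absorb compact letter display.
4. **Ordination.** Bray–Curtis dissimilarity
   ($d_{ij} = \sum_k |x_{ik}-x_{jk}| / \sum_k (x_{ik}+x_{jk})$), NMDS by
   iterative isotonic regression minimising Kruskal stress-1 (best of 20
   random starts, via `vegan::metaMDS`/`monoMDS`), and PCA of the nine
   z-scored water-chemistry variables with per-variable contributions
   ($100\,\ell_{vc}^2 / \sum_v \ell_{vc}^2$ per component).
5. **Chemistry–community association.** Mantel tests between community
   Bray–Curtis and Euclidean distance on z-scored chemistry (single
   variables or all nine), statistic = Pearson correlation of the distance
   triangles, one-sided permutation p over 9999 permutations; and a Pearson
   screen between chemistry and rank-aggregated relative abundances with
   two-sided t-based p (df = n−2), left unadjusted per-cell (a BH option
   exists).
6. **Co-occurrence networks.** Per site, the 11 monthly samples of the
   pooled bacterial/fungal/protist table are filtered (taxon present in ≥ 7
   months AND ≥ 12 total reads, both inclusive), correlated all-pairs by
   Spearman rank correlation (average ranks on ties; p from the t
   approximation with df = n−2), BH-adjusted over the upper triangle, and
   thresholded: an edge requires |ρ| > 0.7 AND adjusted p < 0.01, both
   strict. Modules come from seeded Louvain modularity maximisation on the
   unweighted graph; topology summaries report node/edge counts, signed-edge
   percentages, average degree, modularity
   $Q = \sum_s (l_s/m - (d_s/2m)^2)$, modules with more than 5 nodes
   (strict), mean unnormalised betweenness, mean within-component closeness
   $(n_c-1)/\sum d$, mean local clustering (degree-1 nodes contribute 0) and
   mean shortest-path distance over connected ordered pairs.
7. **Keystone roles.** Within-module connectivity
   $Z_i = (\kappa_i - \bar\kappa_{s(i)})/\sigma_{\kappa,s(i)}$ and
   among-module connectivity $P_i = 1 - \sum_s (k_{is}/k_i)^2$ classify
   nodes: network hub ($Z_i > 2.5$, $P_i > 0.62$), module hub ($Z_i > 2.5$,
   $P_i \le 0.62$), connector ($Z_i \le 2.5$, $P_i > 0.62$), peripheral
   otherwise.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| rarefaction depth (16S / 18S) | 44465 / 39865 | reads/sample | standard depths for these markers at this sequencing scale; minimum sample total when simulating |
| prevalence filter | ≥ 7 months | samples | a taxon must persist most of the year to support an 11-point correlation |
| abundance filter | ≥ 12 reads | reads | removes taxa too rare for rank correlation to be meaningful |
| edge criterion | \|ρ\| > 0.7, adj. p < 0.01 | — | strong, FDR-controlled monotone association |
| Mantel permutations | 9999 | — | p resolution 10⁻⁴ |
| role thresholds | Z = 2.5, P = 0.62 | — | the standard within/among-module connectivity cut-offs |
| alpha | 0.05 | — | group comparisons and the Pearson screen |

## The synthetic generator

The generator (`scenario_config()`, `simulate_scenario()`) emulates the
processed-data level of the survey — count tables, taxonomy, metadata,
chemistry — not raw reads. Its per-sample model is log-normal
compositional: taxon log-abundances are a baseline draw, scaled up in
spread for core sites; relative abundances are the softmax; counts are
multinomial at Poisson(depth). Planted structure, recorded in a
`planted_truth` object for recovery scoring:

* **Core/edge diversity gradient** (`diversity_gradient`, default 0.5):
  the spread of taxon log-baselines is multiplied by 1.5 in the core pools
  (Site 3–5), reducing evenness and hence Shannon and effective richness
  there — the direction observed in eutrophied pool centres.
* **Seasonal forcing** (`temperature_amplitude`, default 10 °C):
  temperature follows a sinusoid peaking in July; TN, TP, COD~Mn~ and
  Chl *a* get an uplift of `eutrophication_effect` (default 1.5) baseline
  SDs in core sites and in summer.
* **Chemistry-linked taxa** (`chem_link_effect`, default 1.2 log-units per
  SD): a Cyanobacteria-labelled ASV block anti-correlated with
  temperature, an Actinobacteria block positively correlated, and an
  Alveolata block tracking TP — so the Pearson screen and Mantel tests
  have known sign targets at phylum level.
* **Co-occurring guilds** (`n_guilds` = 3 × `guild_size` = 10 bacterial
  ASVs): each guild shares one AR(1) monthly trajectory per site
  (lag-0.3, standardized to unit realized SD, gain 2.2 log-units) plus
  idiosyncratic noise `guild_noise_sd` (default 0.15). Guild members get a
  higher baseline (log-mean 1.3) so counts stay off zero through
  trajectory troughs; ties at zero would otherwise erode the rank
  correlations the network stage depends on. These scales were fixed at
  design time so that, at n = 11 samples and ~3·10⁴ BH-corrected tests,
  within-guild pairs clear the |ρ| > 0.7 / adjusted-p < 0.01 criterion:
  detectability by the network stage is part of the scenario's definition,
  not an afterthought.
* **Contaminants**: Metazoa, Streptophyta, Rhodophyta, Opisthokonta and
  unassigned-phylum lineages are planted in the 18S table to exercise the
  non-target filter.

One RNG stream per artifact (chemistry, each count table, taxonomy),
derived from the master seed by fixed labels, so regenerating one artifact
does not shift the others; a fixed seed makes every output byte-identical.

What the generator does **not** emulate: compositional correlation bias
(closure effects), overdispersion beyond multinomial (no
Dirichlet-multinomial), sequencing error or chimeras, realistic taxon
frequency spectra, temporal autocorrelation of non-guild taxa, and any
real covariance between chemistry variables beyond the planted uplifts.
Passing recovery tests therefore show that the pipeline detects the kinds
of structure it claims to detect at realistic scale and noise — not that
real breeding-pool data contain that structure.

## Numerical and design decisions

* **Edge sign.** The edge rule is |ρ| > 0.7, admitting negative edges.
  A positive-only reading of "correlation greater than 0.7" is
  inconsistent with co-occurrence tables that report majority-negative
  edge fractions; the signed reading is the default, and the sign is
  stored per edge.
* **Threshold order.** BH adjustment is applied first, then the p < 0.01
  cut on adjusted values — the stricter of the two defensible orders. A
  raw-p mode exists (`use_adjusted_p = FALSE`).
* **Filter logic.** "Present in fewer than 7 months" and "total below 12
  reads" are removal conditions joined so that a taxon is retained only if
  it passes both (AND-retention), the stricter reading; both bounds are
  inclusive and covered by boundary tests.
* **Rarefy-then-filter.** The prevalence/abundance filter runs on rarefied
  counts by default; whether to filter before or after rarefaction is a
  genuinely open choice and is configurable.
* **Zi = 2.5 boundary.** The hub definitions use Z > 2.5 and the
  peripheral definition Z < 2.5, leaving Z = 2.5 unassigned; it is placed
  on the non-hub side so classification is total. Likewise P = 0.62 is
  non-connector.
* **Zi with degenerate modules.** When a module's within-module degrees
  have zero SD (including singleton modules), Z_i = 0 by convention.
* **Mantel flavour.** Pearson on distance vectors (the common default),
  with a Spearman option; one-sided greater-than alternative, standard for
  distance–distance association. Per-variable chemistry distances are
  Euclidean on z-scores — a configuration choice, not an inference.
* **Spearman p.** t approximation with df = n−2 and average ranks;
  exact-permutation p is unnecessary given the |ρ| threshold dominates at
  n = 11.
* **Degenerate ANOVA inputs.** All-identical values give a flat
  comparison (p = 1, one letter); zero within-group variance with
  distinct means gives F = ∞ reported as p = 0, flagged.
* **Disconnected graphs.** Closeness and path metrics are computed within
  components ((n_c−1)/Σd per node; mean over connected ordered pairs);
  betweenness is unnormalised. Edgeless graphs produce zeroed, flagged
  summaries.
* **NMDS orientation.** Stress is rotation-invariant; coordinates are
  centred and PC-rotated purely for reproducible output.
* **ANOVA replication.** Site comparisons pool the 11 monthly values per
  site as replicates (months as independent replicates); no
  repeated-measures structure is modelled.

## Problem sizes used by the test suite

Module tests run a scaled-down scenario (60 + 40 ASVs, 4,000 reads/sample)
chosen so each property is still identifiable; oracle comparisons use ≥ 50
random instances of ≤ 12 taxa or nodes against independent brute-force
implementations at 10⁻¹⁰ tolerance. The planted-recovery and determinism
checks run the full default scenario (88 samples, 280 ASVs, 50,000
reads/sample) over 10 seeds for recovery and 2 runs for byte-identity.
Null calibrations use 500–1000 replicates (999 permutations per Mantel
test); permutation p values sit on a k/1000 grid and are de-discretized
exactly (subtracting U(0, 1/1000)) before Kolmogorov–Smirnov comparison
with U(0, 1).

## Known limitations

Spearman co-occurrence on compositional data is blind to closure-induced
spurious correlation (SparCC-style compositionality-aware estimators are
out of scope); n = 11 time points bounds detectable associations to very
strong ones, which the FDR correction sharpens further; Louvain is a
greedy heuristic whose partition can vary between seeds on weak module
structure (it is seeded for reproducibility); and the Mantel test's power
depends on how chemistry distances are formed. The per-cell unadjusted
Pearson screen mirrors common practice of displaying p < 0.05 heatmaps and
should be read as descriptive, not confirmatory — the BH option exists for
the stricter reading.
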