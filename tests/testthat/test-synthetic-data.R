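# Generator: design structure, determinism, planted effect directions.

test_that("metadata follows the sampling design", {
  md <- generate_metadata(scenario_config(seed = 1))
  expect_equal(nrow(md), 88)
  expect_equal(length(unique(md$site)), 8)
  expect_false("Feb" %in% md$month)
  expect_equal(unique(md$season[md$month == "Jun"]), "Summer")
  expect_equal(unique(md$season[md$month %in% c("Jan", "Dec")]), "Winter")
  expect_equal(unique(md$season[md$month == "Mar"]), "Spring")
  expect_equal(unique(md$season[md$month == "Sep"]), "Autumn")
  expect_setequal(unique(md$zone[md$site %in% c("Site3", "Site4", "Site5")]), "core")
  expect_setequal(unique(md$zone[md$site %in% c("Inlet", "Site1", "Outlet")]), "edge")
  expect_false(anyDuplicated(md$sample_id) > 0)

  one <- generate_metadata(scenario_config(seed = 1, n_sites = 1, months = "Jan"))
  expect_equal(nrow(one), 1)
  expect_equal(one$season, "Winter")
})

test_that("february and oversized guilds are rejected", {
  expect_error(scenario_config(months = c("Jan", "Feb")), "February")
  expect_error(scenario_config(n_guilds = 30, guild_size = 10,
                               n_asvs_bacteria = 100), "exceeds")
  expect_error(scenario_config(diversity_gradient = -1), "non-negative")
})

test_that("identical configs give byte-identical bundles", {
  a <- simulate_scenario(small_config(seed = 11))
  b <- simulate_scenario(small_config(seed = 11))
  expect_identical(a$chemistry, b$chemistry)
  expect_identical(a$counts_16s, b$counts_16s)
  expect_identical(a$counts_18s, b$counts_18s)
  expect_identical(a$taxonomy, b$taxonomy)
  c <- simulate_scenario(small_config(seed = 12))
  expect_false(identical(a$counts_16s, c$counts_16s))
})

test_that("chemistry carries the planted eutrophication and season structure", {
  # direction checked across seeds (Monte-Carlo over the generator)
  tp_diff <- temp_diff <- numeric(10)
  for (s in 1:10) {
    cfg <- small_config(seed = s)
    md <- generate_metadata(cfg)
    ch <- generate_chemistry(cfg, md)
    tp_diff[s] <- mean(ch$TP[md$zone == "core"]) - mean(ch$TP[md$zone == "edge"])
    temp_diff[s] <- mean(ch$Temp[md$season == "Summer"]) -
      mean(ch$Temp[md$season == "Winter"])
  }
  expect_true(all(tp_diff > 0))
  expect_true(all(temp_diff > 0))

  # null scenario: site means equal in expectation
  null_diffs <- sapply(1:10, function(s) {
    cfg <- null_scenario(seed = s, n_asvs_bacteria = 60L, n_asvs_euk = 40L,
                         sequencing_depth_mean = 4000L)
    md <- generate_metadata(cfg)
    ch <- generate_chemistry(cfg, md)
    mean(ch$TP[md$zone == "core"]) - mean(ch$TP[md$zone == "edge"])
  })
  expect_gt(t.test(null_diffs)$p.value, 0.01)
})

test_that("count tables respect the depth model and carry planted diversity", {
  sim <- cached_sim(small_config(seed = 3))
  totals <- rowSums(sim$counts_16s)
  mu <- small_config(seed = 3)$sequencing_depth_mean
  expect_true(all(abs(totals - mu) < 3 * sqrt(mu) + 1e-9))
  expect_true(all(sim$counts_16s >= 0))
  expect_true(all(sim$counts_16s == round(sim$counts_16s)))

  # planted gradient: core Shannon < edge Shannon in >= 9/10 seeds
  hits <- sapply(1:10, function(s) {
    sim <- cached_sim(small_config(seed = s))
    sh <- apply(as.matrix(unclass(sim$counts_16s)), 1, shannon)
    mean(sh[sim$metadata$zone == "edge"]) > mean(sh[sim$metadata$zone == "core"])
  })
  expect_gte(sum(hits), 9)
})

test_that("null scenario carries no diversity gradient", {
  # two-sided test across seeds, not significant at alpha = 0.01
  diffs <- sapply(1:20, function(s) {
    cfg <- null_scenario(seed = 100 + s, n_asvs_bacteria = 60L, n_asvs_euk = 40L,
                         sequencing_depth_mean = 4000L)
    sim <- simulate_scenario(cfg)
    sh <- apply(as.matrix(unclass(sim$counts_16s)), 1, shannon)
    mean(sh[sim$metadata$zone == "edge"]) - mean(sh[sim$metadata$zone == "core"])
  })
  expect_gt(t.test(diffs)$p.value, 0.01)
})

test_that("zero guild noise gives perfectly rank-correlated guild members", {
  cfg <- small_config(seed = 5, guild_noise_sd = 0)
  frame <- generate_metadata(cfg)
  chem <- generate_chemistry(cfg, frame)
  # compare latent structure at high depth so count noise is negligible
  cfg2 <- small_config(seed = 5, guild_noise_sd = 0, sequencing_depth_mean = 2e5)
  sim <- simulate_scenario(cfg2)
  g1 <- names(sim$truth$guild_membership)[sim$truth$guild_membership == 1]
  ids <- sim$metadata$sample_id[sim$metadata$site == "Site1"]
  m <- as.matrix(unclass(sim$counts_16s))[ids, g1]
  rr <- cor(m, method = "spearman")
  expect_true(all(rr[upper.tri(rr)] > 0.99))
})

test_that("planted truth is self-consistent and sufficient for scoring", {
  sim <- cached_sim(small_config(seed = 3))
  tr <- sim$truth
  expect_s3_class(tr, "planted_truth")
  # every planted pair lies within one guild
  ga <- tr$guild_membership[tr$planted_pairs$taxon_a]
  gb <- tr$guild_membership[tr$planted_pairs$taxon_b]
  expect_true(all(ga == gb))
  expect_true(all(ga == tr$planted_pairs$guild))
  expect_setequal(names(tr$site_zone), sim$config$sites)
  expect_true(all(tr$chem_taxon_links$taxon %in% sim$taxonomy$phylum))
})

test_that("scenario bundles round-trip through disk", {
  sim <- cached_sim(small_config(seed = 3))
  dir <- tempfile("bundle_")
  write_scenario(sim, dir)
  back <- read_count_table(file.path(dir, "asv_16s.tsv"))
  expect_equal(unclass(back)[, ], unclass(sim$counts_16s)[, ])
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  expect_equal(tax$taxon_id, sim$taxonomy$taxon_id)
  unlink(dir, recursive = TRUE)
})
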