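# Count-table validation, rarefaction, taxon filters, aggregation.

test_that("count_table validates shape, ids and cell values", {
  m <- matrix(c(1, 2, 3, 4), 2, dimnames = list(c("s1", "s2"), c("t1", "t2")))
  ct <- count_table(m)
  expect_s3_class(ct, "count_table")
  m_neg <- m; m_neg[2, 1] <- -1
  expect_error(count_table(m_neg), "s2.*t1")
  m_frac <- m; m_frac[1, 2] <- 1.5
  expect_error(count_table(m_frac), "non-integer")
  expect_error(count_table(matrix(1:4, 2, dimnames = list(c("a", "a"), c("x", "y")))),
               "duplicate sample")
})

test_that("TSV round-trip preserves a count table", {
  ct <- count_table(matrix(c(5L, 0L, 2L, 9L), 2,
                           dimnames = list(c("s1", "s2"), c("t1", "t2"))))
  path <- tempfile(fileext = ".tsv")
  write_count_table(ct, path)
  back <- read_count_table(path)
  expect_equal(unclass(back)[, ], unclass(ct)[, ])
  # negative cell named on read
  writeLines(c("asv_id\ts1\ts2", "t1\t3\t-2"), path)
  expect_error(read_count_table(path), "negative")
  unlink(path)
})

test_that("rarefy returns exact depth, drops shallow samples, is seeded", {
  m <- matrix(c(50L, 50L, 3L, 2L), 2, byrow = TRUE,
              dimnames = list(c("deep", "shallow"), c("t1", "t2")))
  ct <- count_table(m)
  r <- rarefy(ct, 20, seed = 7)
  expect_equal(rownames(r), "deep")
  expect_equal(sum(r), 20)
  expect_equal(attr(r, "dropped_samples"), "shallow")
  expect_identical(unclass(rarefy(ct, 20, seed = 7))[, ],
                   unclass(rarefy(ct, 20, seed = 7))[, ])
  # total exactly equal to depth -> unchanged
  r2 <- rarefy(ct, 100, seed = 1)
  expect_equal(unclass(r2)["deep", ], c(t1 = 50, t2 = 50))
  # depth 1 -> exactly one taxon with count 1 in every retained sample
  r3 <- rarefy(ct, 1, seed = 1)
  expect_true(all(rowSums(r3) == 1))
  expect_true(all(rowSums(unclass(r3) > 0) == 1))
  expect_error(rarefy(ct, 1000), "no samples retained")
})

test_that("rarefaction matches the hypergeometric expectation", {
  ct <- count_table(matrix(c(900L, 100L), 1, dimnames = list("s", c("a", "b"))))
  draws <- vapply(1:1000, function(s) unclass(rarefy(ct, 100, seed = s))[1, "a"],
                  numeric(1))
  # mean of 'a' ~ 90; hypergeometric SD with N=1000, K=900, n=100
  sd_hyper <- sqrt(100 * 0.9 * 0.1 * (1000 - 100) / (1000 - 1))
  expect_lt(abs(mean(draws) - 90), 3 * sd_hyper / sqrt(1000))
})

test_that("non-target protist filter removes the flagged lineages only", {
  m <- matrix(1L, 2, 3, dimnames = list(c("s1", "s2"), c("a1", "a2", "a3")))
  tax <- data.frame(taxon_id = c("a1", "a2", "a3"),
                    domain = "Eukaryota",
                    phylum = c("Streptophyta", "Alveolata", "Chlorophyta"),
                    class = "x", order = "x", family = "x",
                    genus = c("g1", "g2", "g3"))
  out <- filter_nontarget_protists(count_table(m), tax)
  expect_equal(colnames(out), c("a2", "a3"))
  # no flagged lineages -> no-op
  tax2 <- tax; tax2$phylum <- c("Alveolata", "Rhizaria", "Chlorophyta")
  out2 <- filter_nontarget_protists(count_table(m), tax2)
  expect_equal(colnames(out2), colnames(m))
  # unassigned at the configured rank removed
  tax3 <- tax2; tax3$phylum[2] <- "unassigned"
  expect_equal(colnames(filter_nontarget_protists(count_table(m), tax3)),
               c("a1", "a3"))
  # missing taxon -> error listing ids
  expect_error(filter_nontarget_protists(count_table(m), tax[1:2, ]), "a3")
})

test_that("synthetic contaminants are exactly the removed set", {
  sim <- cached_sim(small_config(seed = 3))
  filtered <- filter_nontarget_protists(sim$counts_18s, sim$taxonomy)
  nontarget <- sim$taxonomy$taxon_id[sim$taxonomy$group == "nontarget"]
  expect_setequal(attr(filtered, "removed_taxa"), nontarget)
  expect_setequal(colnames(filtered),
                  setdiff(colnames(sim$counts_18s), nontarget))
  # idempotent
  twice <- filter_nontarget_protists(filtered, sim$taxonomy)
  expect_equal(colnames(twice), colnames(filtered))
})

test_that("prevalence/abundance filter uses inclusive boundaries", {
  # 11 monthly samples, hand-built taxa at the boundaries
  m <- matrix(0L, 11, 4, dimnames = list(paste0("m", 1:11),
                                         c("keep_boundary", "low_total",
                                           "few_months", "all_zero")))
  m[1:7, "keep_boundary"] <- c(2L, 2L, 2L, 2L, 2L, 1L, 1L)   # 7 months, 12 reads
  m[1:11, "low_total"] <- 1L                                  # 11 months, 11 reads
  m[1:6, "few_months"] <- 10L                                 # 6 months, 60 reads
  out <- prevalence_abundance_filter(count_table(m))
  expect_equal(colnames(out), "keep_boundary")
  # idempotent
  expect_equal(colnames(prevalence_abundance_filter(out)), "keep_boundary")
})

test_that("rank aggregation yields proportions that sum to one", {
  m <- matrix(c(30L, 70L, 25L, 75L), 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("t1", "t2")))
  tax <- data.frame(taxon_id = c("t1", "t2"), domain = "Bacteria",
                    phylum = c("P1", "P1"), class = "c", order = "o",
                    family = "f", genus = c("g1", "g2"))
  one <- aggregate_relative_abundance(count_table(m), tax, "phylum")
  expect_equal(unname(one[, "P1"]), c(1, 1))
  tax$phylum <- c("P1", "P2")
  two <- aggregate_relative_abundance(count_table(m), tax, "phylum")
  expect_equal(unname(two["s1", ]), c(0.30, 0.70))
  expect_equal(unname(two["s2", ]), c(0.25, 0.75))

  sim <- cached_sim(small_config(seed = 3))
  ra <- aggregate_relative_abundance(sim$counts_16s, sim$taxonomy, "phylum")
  expect_true(all(abs(rowSums(ra) - 1) < 1e-12))

  zero <- matrix(c(1L, 0L), 2, 1, dimnames = list(c("s1", "s2"), "t1"))
  expect_error(aggregate_relative_abundance(count_table(zero), tax[1, ], "phylum"),
               "zero-total")
})
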