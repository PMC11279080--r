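# Spearman correlation matrices, BH adjustment, graph construction, module
# detection, topology metrics, Zi-Pi and role classification.

test_that("correlation matrices match the rank oracle and exclude the diagonal", {
  x <- c(3, 1, 4, 1, 5)
  y <- c(2, 7, 1, 8, 2)
  m <- cbind(a = x, b = y, c = c(1, 2, 3, 4, 5))
  rownames(m) <- paste0("s", 1:5)
  cm <- correlation_matrices(count_table(m))
  expect_equal(cm$r["a", "b"], oracle_spearman(x, y), tolerance = 1e-12)
  expect_true(all(is.na(diag(cm$r))))
  expect_true(all(is.na(diag(cm$p))))
  # strictly increasing transform -> r = 1 (and p = 0 at the saturation point)
  m2 <- cbind(a = 1:5, b = (1:5)^3)
  rownames(m2) <- paste0("s", 1:5)
  cm2 <- correlation_matrices(count_table(m2))
  expect_equal(cm2$r["a", "b"], 1)
  expect_equal(cm2$p["a", "b"], 0)
  # constant taxon -> undefined pairs
  m3 <- cbind(a = c(1, 2, 3, 4, 5), b = rep(2, 5))
  rownames(m3) <- paste0("s", 1:5)
  cm3 <- correlation_matrices(count_table(m3))
  expect_true(is.na(cm3$r["a", "b"]))
  expect_true(is.na(cm3$p["a", "b"]))
})

test_that("spearman r agrees with the oracle on random count vectors", {
  set.seed(14)
  for (i in 1:50) {
    m <- matrix(rpois(22, 5), 11, 2, dimnames = list(paste0("s", 1:11), c("a", "b")))
    if (sd(m[, 1]) == 0 || sd(m[, 2]) == 0) next
    cm <- correlation_matrices(count_table(m))
    expect_equal(cm$r["a", "b"], oracle_spearman(m[, 1], m[, 2]), tolerance = 1e-12)
  }
})

test_that("bh adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(15)
  for (i in 1:50) {
    p <- runif(sample(2:12, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("edges require |r| strictly above and adjusted p strictly below threshold", {
  taxa <- c("a", "b", "c")
  r <- matrix(0, 3, 3, dimnames = list(taxa, taxa))
  p <- matrix(1, 3, 3, dimnames = list(taxa, taxa))
  r["a", "b"] <- r["b", "a"] <- 0.7       # boundary: excluded
  p["a", "b"] <- p["b", "a"] <- 1e-6
  r["a", "c"] <- r["c", "a"] <- -0.9      # |r| rule admits negative edges
  p["a", "c"] <- p["c", "a"] <- 0.001
  g <- build_network(r, p)
  expect_equal(igraph::ecount(g), 1)
  e <- igraph::as_data_frame(g)
  expect_setequal(unlist(e[, c("from", "to")]), c("a", "c"))
  expect_equal(e$sign, "-")
  # p at the threshold: excluded
  p["a", "c"] <- p["c", "a"] <- 0.01
  expect_equal(igraph::ecount(build_network(r, p)), 0)
  # empty graph -> zeroed summary
  s <- topology_summary(build_network(r * 0, p))
  expect_true(s$degenerate)
  expect_equal(s$n_nodes + s$n_edges, 0)
})

test_that("module detection resolves planted block structure", {
  # two disjoint 5-cliques
  adj <- matrix(0, 10, 10)
  adj[1:5, 1:5] <- 1; adj[6:10, 6:10] <- 1
  diag(adj) <- 0
  dimnames(adj) <- list(paste0("n", 1:10), paste0("n", 1:10))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  part <- detect_modules(g, seed = 3)
  expect_equal(length(unique(part)), 2)
  expect_equal(length(unique(part[paste0("n", 1:5)])), 1)
  expect_equal(length(unique(part[paste0("n", 6:10)])), 1)
  # complete graph: one module
  full <- igraph::make_full_graph(6)
  igraph::V(full)$name <- paste0("n", 1:6)
  expect_equal(length(unique(detect_modules(full, seed = 1))), 1)
})

test_that("modularity matches closed forms and the brute-force oracle", {
  # twin triangles: Q = 2 (3/6 - (6/12)^2) = 0.5
  adj <- matrix(0, 6, 6)
  adj[1:3, 1:3] <- 1; adj[4:6, 4:6] <- 1; diag(adj) <- 0
  dimnames(adj) <- list(paste0("n", 1:6), paste0("n", 1:6))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  part <- setNames(rep(1:2, each = 3), paste0("n", 1:6))
  expect_equal(as.numeric(modularity_q(g, part)), 0.5, tolerance = 1e-12)
  expect_equal(as.numeric(modularity_q(g, setNames(rep(1, 6), paste0("n", 1:6)))), 0)
  set.seed(16)
  for (i in 1:50) {
    fx <- random_graph_fixture(sample(5:10, 1))
    if (igraph::ecount(fx$graph) == 0) next
    mem <- setNames(sample(1:3, length(fx$names), replace = TRUE), fx$names)
    expect_equal(as.numeric(modularity_q(fx$graph, mem)),
                 oracle_modularity(fx$adj, mem[fx$names]), tolerance = 1e-12)
    # cross-check against igraph's own modularity
    expect_equal(as.numeric(modularity_q(fx$graph, mem)),
                 igraph::modularity(fx$graph, mem[fx$names]), tolerance = 1e-12)
  }
})

test_that("topology summary matches closed forms on tiny graphs", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  s <- topology_summary(tri, setNames(rep(1, 3), c("a", "b", "c")))
  expect_equal(s$average_degree, 2)
  expect_equal(s$avg_clustering, 1)
  expect_equal(s$avg_path_distance, 1)

  path3 <- igraph::graph_from_literal(a - b - c)
  s2 <- topology_summary(path3, setNames(rep(1, 3), c("a", "b", "c")))
  expect_equal(s2$avg_clustering, 0)
  expect_equal(s2$avg_path_distance, 4 / 3)
  expect_equal(s2$avg_betweenness, 1 / 3)
  # closeness: ends 2/3, middle 1
  expect_equal(s2$avg_closeness, (2 / 3 + 2 / 3 + 1) / 3)

  # a 5-node module is not counted as > 5
  part <- setNames(c(rep(1, 5), rep(2, 6)), paste0("n", 1:11))
  g <- igraph::make_ring(11)
  igraph::V(g)$name <- paste0("n", 1:11)
  expect_equal(topology_summary(g, part)$n_modules_gt5, 1)
})

test_that("topology metrics equal brute-force recomputation on random graphs", {
  set.seed(17)
  for (i in 1:50) {
    fx <- random_graph_fixture(sample(4:12, 1))
    if (igraph::ecount(fx$graph) == 0) next
    part <- detect_modules(fx$graph, seed = i)
    s <- topology_summary(fx$graph, part)
    expect_equal(s$avg_clustering, mean(oracle_clustering(fx$adj)), tolerance = 1e-10)
    expect_equal(s$avg_betweenness, mean(oracle_betweenness(fx$adj)), tolerance = 1e-10)
    expect_equal(s$avg_closeness, mean(oracle_closeness(fx$adj)), tolerance = 1e-10)
    expect_equal(s$avg_path_distance, oracle_avg_path(fx$adj), tolerance = 1e-10)
    expect_equal(s$average_degree, 2 * igraph::ecount(fx$graph) / igraph::vcount(fx$graph))
  }
})

test_that("zi and pi match direct formulas and the oracle", {
  # node with all links inside its module -> Pi = 0
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  zp <- zi_pi(tri, setNames(rep(1, 3), c("a", "b", "c")))
  expect_equal(zp$Pi, rep(0, 3))
  expect_equal(zp$Zi, rep(0, 3))   # equal within-module degree -> Zi = 0

  # degree 4 split 2/2 across two modules -> Pi = 0.5
  g <- igraph::graph_from_literal(hub - a, hub - b, hub - c, hub - d)
  part <- setNames(c(1, 1, 1, 2, 2), c("hub", "a", "b", "c", "d"))
  zp2 <- zi_pi(g, part)
  expect_equal(zp2$Pi[zp2$node == "hub"], 0.5)

  set.seed(18)
  for (i in 1:50) {
    fx <- random_graph_fixture(sample(5:12, 1))
    if (igraph::ecount(fx$graph) == 0) next
    part <- detect_modules(fx$graph, seed = i)
    zp <- zi_pi(fx$graph, part)
    orc <- oracle_zi_pi(fx$adj, part[fx$names])
    expect_equal(zp$Zi, orc$zi, tolerance = 1e-10)
    expect_equal(zp$Pi, orc$pi, tolerance = 1e-10)
  }
})

test_that("role classification partitions the Zi-Pi plane with correct boundaries", {
  expect_equal(classify_roles(3.0, 0.7), "network_hub")
  expect_equal(classify_roles(3.0, 0.1), "module_hub")
  expect_equal(classify_roles(0.0, 0.0), "peripheral")
  expect_equal(classify_roles(0.0, 0.9), "connector")
  # boundaries: Zi = 2.5 is non-hub, Pi = 0.62 is non-connector
  expect_equal(classify_roles(2.5, 0.62), "peripheral")
  expect_equal(classify_roles(2.5, 0.7), "connector")
  expect_equal(classify_roles(2.6, 0.62), "module_hub")
  # exactly one role everywhere on a grid
  grid <- expand.grid(zi = c(-1, 0, 2.49, 2.5, 2.51, 5),
                      pi = c(0, 0.5, 0.61, 0.62, 0.63, 1))
  roles <- classify_roles(grid$zi, grid$pi)
  expect_true(all(roles %in% c("network_hub", "module_hub", "connector", "peripheral")))
  expect_equal(length(roles), nrow(grid))
  expect_error(classify_roles(NA, 0.5), "finite")
})

test_that("every built edge satisfies the threshold predicate", {
  sim <- cached_sim(small_config(seed = 3))
  net <- site_network(pooled_site_table(sim, "Site2"), seed = 5)
  if (igraph::ecount(net$graph) > 0) {
    e <- igraph::as_data_frame(net$graph)
    expect_true(all(abs(e$spearman_r) > 0.7))
    expect_true(all(e$p_adjusted < 0.01))
    expect_true(all(e$sign == ifelse(e$spearman_r > 0, "+", "-")))
  }
  expect_equal(net$summary$average_degree,
               2 * net$summary$n_edges / max(net$summary$n_nodes, 1))
  expect_equal(net$summary$pct_positive + net$summary$pct_negative, 100)
})

test_that("dropping one month leaves the network contract intact", {
  sim <- cached_sim(small_config(seed = 3))
  tab <- pooled_site_table(sim, "Site1")
  tab10 <- count_table(as.matrix(unclass(tab))[-4, , drop = FALSE])
  net <- site_network(tab10, min_months = 6, seed = 5)
  if (igraph::ecount(net$graph) > 0) {
    e <- igraph::as_data_frame(net$graph)
    expect_true(all(abs(e$spearman_r) > 0.7 & e$p_adjusted < 0.01))
  }
  expect_s3_class(net$summary, "topology_summary")
})

test_that("graphml export round-trips node roles and edge signs", {
  sim <- cached_sim(small_config(seed = 3))
  net <- site_network(pooled_site_table(sim, "Site1"), seed = 5)
  expect_gt(igraph::vcount(net$graph), 0)
  path <- tempfile(fileext = ".graphml")
  export_graphml(net$graph, path, node_table = net$nodes)
  back <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(net$graph))
  expect_setequal(igraph::vertex_attr(back, "role"), unique(net$nodes$role))
  expect_true(all(igraph::edge_attr(back, "sign") %in% c("+", "-")))
  unlink(path)
})
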