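# Per-site co-occurrence networks: Spearman correlation with BH-FDR
# thresholding, Louvain module detection, topological summaries and
# Zi-Pi keystone role classification.

#' All-pairs Spearman correlation and p matrices for one site
#'
#' Spearman rank correlation (average ranks on ties) between every taxon
#' pair across the site's monthly samples; two-sided p from the t
#' approximation with df = n - 2. Pairs involving a constant taxon are
#' undefined (NA) and can never become edges; the diagonal is excluded.
#'
#' @param site_table [count_table()] of one site's monthly samples (already
#'   prevalence/abundance filtered; taxa pooled across organism groups).
#' @return List with `r` and `p` matrices and `n` (number of samples).
#' @export
correlation_matrices <- function(site_table) {
  m <- if (inherits(site_table, "count_table")) as_count_matrix(site_table) else as.matrix(site_table)
  n <- nrow(m)
  if (n < 4) stop_f("need at least 4 samples, have %d", n)
  r <- suppressWarnings(cor(m, method = "spearman"))
  r2 <- pmin(r^2, 1)
  tval <- r * sqrt(n - 2) / sqrt(pmax(1 - r2, .Machine$double.eps))
  p <- 2 * pt(-abs(tval), df = n - 2)
  p[r2 >= 1 - 1e-15] <- 0
  p[!is.finite(r)] <- NA
  diag(r) <- NA
  diag(p) <- NA
  list(r = r, p = p, n = n)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values numeric vector of p values in \[0, 1\] (NA allowed).
#' @return Adjusted p values, monotone and capped at 1.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stop_f("p values must be numeric")
  bad <- is.finite(p_values) & (p_values < 0 | p_values > 1)
  if (any(bad)) stop_f("p values outside [0, 1]")
  p.adjust(p_values, method = "BH")
}

# BH over the upper triangle of a symmetric p matrix, mirrored back.
adjust_p_matrix <- function(p) {
  ut <- upper.tri(p)
  adj <- p
  adj[ut] <- bh_adjust(p[ut])
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  adj
}

#' Build the thresholded co-occurrence graph
#'
#' An edge joins two taxa iff |r| > `r_threshold` AND the (adjusted) p is
#' < `p_threshold` — both strict. Edge sign is the sign of r; taxa left
#' without any edge are excluded from the node set.
#'
#' @param r Spearman correlation matrix.
#' @param p_adjusted matrix of BH-adjusted p values aligned with `r`.
#' @param r_threshold,p_threshold edge criteria (study defaults 0.7, 0.01).
#' @param p_raw optional matrix of raw p values stored per edge.
#' @param taxonomy optional taxonomy data frame; stores group/phylum/genus
#'   as node attributes.
#' @return An [igraph::graph] with edge attributes `spearman_r`, `p_raw`,
#'   `p_adjusted`, `sign` and node attribute `name`.
#' @export
build_network <- function(r, p_adjusted, r_threshold = 0.7, p_threshold = 0.01,
                          p_raw = NULL, taxonomy = NULL) {
  stopifnot(is.matrix(r), identical(dim(r), dim(p_adjusted)))
  taxa <- colnames(r)
  ut <- which(upper.tri(r), arr.ind = TRUE)
  rv <- r[upper.tri(r)]
  pv <- p_adjusted[upper.tri(p_adjusted)]
  sel <- is.finite(rv) & is.finite(pv) & abs(rv) > r_threshold & pv < p_threshold
  if (!any(sel)) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  } else {
    edges <- data.frame(from = taxa[ut[sel, 1]], to = taxa[ut[sel, 2]],
                        spearman_r = rv[sel], p_adjusted = pv[sel],
                        sign = ifelse(rv[sel] > 0, "+", "-"),
                        stringsAsFactors = FALSE)
    if (!is.null(p_raw)) edges$p_raw <- p_raw[upper.tri(p_raw)][sel]
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  }
  if (!is.null(taxonomy) && igraph::vcount(g) > 0) {
    idx <- match(igraph::V(g)$name, taxonomy$taxon_id)
    for (col in intersect(c("group", "phylum", "genus"), names(taxonomy)))
      g <- igraph::set_vertex_attr(g, col, value = taxonomy[[col]][idx])
  }
  g
}

#' Detect modules by greedy modularity optimisation
#'
#' Louvain-style multi-level optimisation on the unweighted, unsigned
#' graph, seeded for reproducibility.
#'
#' @param graph an [igraph::graph].
#' @param seed RNG seed.
#' @return Named integer vector of module ids (attribute `"modularity"`
#'   holds Q for the partition).
#' @export
detect_modules <- function(graph, seed = 1L) {
  if (igraph::vcount(graph) == 0) return(structure(integer(0), modularity = 0))
  set.seed(seed)
  cl <- igraph::cluster_louvain(graph, weights = NA)
  membership <- igraph::membership(cl)
  out <- setNames(as.integer(membership), names(membership))
  attr(out, "modularity") <- modularity_q(graph, out)
  out
}

#' Newman modularity of a partition
#'
#' \eqn{Q = \sum_s (l_s / m - (d_s / 2m)^2)} with \eqn{l_s} the
#' intra-module edge count, \eqn{d_s} the total degree in module s and m
#' the number of edges. An edgeless graph yields 0 (flagged).
#'
#' @param graph an [igraph::graph].
#' @param partition named module ids covering all nodes.
#' @return Q (with attribute `"degenerate"` = TRUE when m = 0).
#' @export
modularity_q <- function(graph, partition) {
  n <- igraph::vcount(graph)
  if (length(partition) != n || !all(igraph::V(graph)$name %in% names(partition)))
    stop_f("partition must cover all nodes")
  m <- igraph::ecount(graph)
  if (m == 0) return(structure(0, degenerate = TRUE))
  mem <- partition[igraph::V(graph)$name]
  el <- igraph::as_edgelist(graph)
  mods <- sort(unique(mem))
  l_s <- vapply(mods, function(s)
    sum(mem[el[, 1]] == s & mem[el[, 2]] == s), numeric(1))
  deg <- igraph::degree(graph)
  d_s <- vapply(mods, function(s) sum(deg[mem[igraph::V(graph)$name] == s]), numeric(1))
  sum(l_s / m - (d_s / (2 * m))^2)
}

#' Topological summary of a co-occurrence network
#'
#' Computes the standard per-network descriptors: node and edge counts,
#' percent positive/negative edges, average degree, modularity, number of
#' modules with more than 5 nodes (strict), mean unnormalised betweenness
#' centrality, mean within-component closeness ((n_c - 1) / sum of
#' distances), mean local clustering coefficient (degree-1 nodes contribute
#' 0) and mean shortest-path distance over connected ordered pairs.
#'
#' @param graph an [igraph::graph].
#' @param partition module ids from [detect_modules()].
#' @return One-row data frame of class `topology_summary`.
#' @export
topology_summary <- function(graph, partition = NULL) {
  n <- igraph::vcount(graph)
  m <- igraph::ecount(graph)
  if (n == 0 || m == 0) {
    out <- data.frame(n_nodes = n, n_edges = m, pct_positive = 0,
                      pct_negative = 0, average_degree = 0, modularity = 0,
                      n_modules_gt5 = 0L, avg_betweenness = 0,
                      avg_closeness = 0, avg_clustering = 0,
                      avg_path_distance = 0, degenerate = TRUE)
    class(out) <- c("topology_summary", class(out))
    return(out)
  }
  if (is.null(partition)) partition <- detect_modules(graph)
  signs <- igraph::edge_attr(graph, "sign")
  pct_pos <- if (is.null(signs)) 100 else 100 * mean(signs == "+")
  D <- igraph::distances(graph)
  finite_off <- is.finite(D) & row(D) != col(D)
  closeness_i <- vapply(seq_len(n), function(i) {
    reach <- finite_off[i, ]
    if (!any(reach)) 0 else sum(reach) / sum(D[i, reach])
  }, numeric(1))
  clus <- igraph::transitivity(graph, type = "localundirected", isolates = "zero")
  out <- data.frame(
    n_nodes = n,
    n_edges = m,
    pct_positive = pct_pos,
    pct_negative = 100 - pct_pos,
    average_degree = 2 * m / n,
    modularity = as.numeric(modularity_q(graph, partition)),
    n_modules_gt5 = sum(table(partition) > 5),
    avg_betweenness = mean(igraph::betweenness(graph, directed = FALSE,
                                               normalized = FALSE)),
    avg_closeness = mean(closeness_i),
    avg_clustering = mean(clus),
    avg_path_distance = if (any(finite_off)) mean(D[finite_off]) else 0,
    degenerate = FALSE
  )
  class(out) <- c("topology_summary", class(out))
  out
}

#' Within-module (Zi) and among-module (Pi) connectivity
#'
#' \eqn{Z_i = (\kappa_i - \bar\kappa_{s(i)}) / \sigma_{\kappa, s(i)}} with
#' \eqn{\kappa_i} the within-module degree of node i (Zi = 0 when the
#' module's \eqn{\sigma} is 0), and
#' \eqn{P_i = 1 - \sum_s (k_{is} / k_i)^2} with \eqn{k_{is}} the links of i
#' into module s. Roles are assigned from the (Zi, Pi) plane via
#' [classify_roles()].
#'
#' @param graph an [igraph::graph].
#' @param partition module ids covering all nodes.
#' @return Data frame: node, module, degree, within_module_degree, Zi, Pi,
#'   role.
#' @export
zi_pi <- function(graph, partition) {
  n <- igraph::vcount(graph)
  if (length(partition) != n || !all(igraph::V(graph)$name %in% names(partition)))
    stop_f("partition must cover all nodes")
  nodes <- igraph::V(graph)$name
  mem <- partition[nodes]
  adj <- igraph::as_adj_list(graph)
  deg <- igraph::degree(graph)
  kappa <- numeric(n)
  pi_val <- numeric(n)
  for (i in seq_len(n)) {
    nb <- nodes[as.integer(adj[[i]])]
    nb_mod <- mem[nb]
    kappa[i] <- sum(nb_mod == mem[i])
    if (deg[i] == 0) { pi_val[i] <- 0; next }
    frac <- table(nb_mod) / deg[i]
    pi_val[i] <- 1 - sum(frac^2)
  }
  zi <- numeric(n)
  for (s in unique(mem)) {
    idx <- which(mem == s)
    mu <- mean(kappa[idx])
    sdev <- if (length(idx) > 1) sd(kappa[idx]) else 0
    zi[idx] <- if (sdev > 0) (kappa[idx] - mu) / sdev else 0
  }
  data.frame(node = nodes, module = as.integer(mem), degree = as.integer(deg),
             within_module_degree = as.integer(kappa), Zi = zi, Pi = pi_val,
             role = classify_roles(zi, pi_val), stringsAsFactors = FALSE)
}

#' Classify nodes into keystone roles from the Zi-Pi plane
#'
#' network hub: Zi > 2.5 and Pi > 0.62; module hub: Zi > 2.5 and
#' Pi <= 0.62; connector: Zi <= 2.5 and Pi > 0.62; peripheral otherwise.
#' The partition is total: every finite (Zi, Pi) point receives exactly one
#' role (the Zi = 2.5 boundary falls on the non-hub side).
#'
#' @param zi,pi numeric vectors.
#' @param zi_threshold,pi_threshold role thresholds (study values 2.5, 0.62).
#' @return Character vector with values `network_hub`, `module_hub`,
#'   `connector`, `peripheral`.
#' @export
classify_roles <- function(zi, pi, zi_threshold = 2.5, pi_threshold = 0.62) {
  stopifnot(length(zi) == length(pi))
  if (any(!is.finite(zi)) || any(!is.finite(pi)))
    stop_f("Zi and Pi must be finite")
  ifelse(zi > zi_threshold,
         ifelse(pi > pi_threshold, "network_hub", "module_hub"),
         ifelse(pi > pi_threshold, "connector", "peripheral"))
}

#' Export a network as GraphML
#'
#' Node attributes (group, taxonomy, module, degree, Zi, Pi, role) and edge
#' attributes (r, p, sign) travel with the graph.
#'
#' @param graph an [igraph::graph].
#' @param path output path.
#' @param node_table optional [zi_pi()] output merged onto nodes first.
#' @export
export_graphml <- function(graph, path, node_table = NULL) {
  if (!is.null(node_table) && igraph::vcount(graph) > 0) {
    idx <- match(igraph::V(graph)$name, node_table$node)
    for (col in setdiff(names(node_table), "node"))
      graph <- igraph::set_vertex_attr(graph, col, value = node_table[[col]][idx])
  }
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Build one site's network end-to-end
#'
#' Chains [prevalence_abundance_filter()], [correlation_matrices()],
#' BH adjustment over the upper triangle, [build_network()],
#' [detect_modules()], [zi_pi()] and [topology_summary()].
#'
#' @param site_table [count_table()] of one site's monthly samples (taxa
#'   pooled across organism groups, rarefied).
#' @param min_months,min_total_reads prevalence/abundance filter settings.
#' @param r_threshold,p_threshold edge criteria.
#' @param use_adjusted_p threshold on BH-adjusted p (default) or raw p.
#' @param taxonomy optional taxonomy for node attributes.
#' @param seed RNG seed for module detection.
#' @return List of class `site_network`: `graph`, `partition`, `nodes`
#'   ([zi_pi()] table), `summary` ([topology_summary()]), `filtered_table`.
#' @export
site_network <- function(site_table, min_months = 7L, min_total_reads = 12L,
                         r_threshold = 0.7, p_threshold = 0.01,
                         use_adjusted_p = TRUE, taxonomy = NULL, seed = 1L) {
  filtered <- prevalence_abundance_filter(site_table, min_months, min_total_reads)
  if (ncol(filtered) < 2) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(structure(list(graph = g, partition = integer(0),
                          nodes = NULL, summary = topology_summary(g),
                          filtered_table = filtered),
                     class = "site_network"))
  }
  cm <- correlation_matrices(filtered)
  p_adj <- adjust_p_matrix(cm$p)
  g <- build_network(cm$r, if (use_adjusted_p) p_adj else cm$p,
                     r_threshold = r_threshold, p_threshold = p_threshold,
                     p_raw = cm$p, taxonomy = taxonomy)
  partition <- detect_modules(g, seed = seed)
  nodes <- if (igraph::vcount(g) > 0) zi_pi(g, partition) else NULL
  structure(list(graph = g, partition = partition, nodes = nodes,
                 summary = topology_summary(g, partition),
                 filtered_table = filtered),
            class = "site_network")
}

#' @export
print.site_network <- function(x, ...) {
  s <- x$summary
  cat(sprintf("site_network: %d nodes, %d edges (%.1f%% negative), Q = %.3f, %d modules > 5 nodes\n",
              s$n_nodes, s$n_edges, s$pct_negative, s$modularity, s$n_modules_gt5))
  invisible(x)
}

#' Score recovery of planted guild structure by a site network
#'
#' Sensitivity is the fraction of planted within-guild pairs — among those
#' whose both members survived the prevalence/abundance filter — that are
#' edges of the network. The module partition is compared to the planted
#' guild labels by adjusted Rand index over guild members present in the
#' graph.
#'
#' @param net a [site_network()].
#' @param truth a `planted_truth` from the generator.
#' @return List: `sensitivity`, `ari`, `n_pairs_evaluable`, `n_guild_nodes`.
#' @export
score_network_recovery <- function(net, truth) {
  stopifnot(inherits(net, "site_network"))
  pairs <- truth$planted_pairs
  if (is.null(pairs) || nrow(pairs) == 0)
    return(list(sensitivity = NA_real_, ari = NA_real_,
                n_pairs_evaluable = 0L, n_guild_nodes = 0L))
  tested <- colnames(net$filtered_table)
  evaluable <- pairs$taxon_a %in% tested & pairs$taxon_b %in% tested
  g <- net$graph
  nodes <- if (igraph::vcount(g) > 0) igraph::V(g)$name else character(0)
  hit <- vapply(which(evaluable), function(i) {
    a <- pairs$taxon_a[i]; b <- pairs$taxon_b[i]
    a %in% nodes && b %in% nodes &&
      igraph::are_adjacent(g, a, b)
  }, logical(1))
  sens <- if (any(evaluable)) mean(hit) else NA_real_
  guild_nodes <- intersect(nodes, names(truth$guild_membership))
  ari <- if (length(guild_nodes) >= 2) {
    mclust::adjustedRandIndex(net$partition[guild_nodes],
                              truth$guild_membership[guild_nodes])
  } else NA_real_
  list(sensitivity = sens, ari = ari,
       n_pairs_evaluable = sum(evaluable), n_guild_nodes = length(guild_nodes))
}
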