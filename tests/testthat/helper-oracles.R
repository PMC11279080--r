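# Independent brute-force oracles. These deliberately avoid the package's
# implementation paths (and igraph's metrics) so they can serve as
# independent checks on small instances.

oracle_shannon <- function(x) {
  p <- x[x > 0] / sum(x)
  total <- 0
  for (pi in p) total <- total - pi * log(pi)
  total
}

oracle_chao1 <- function(x) {
  s <- 0; f1 <- 0; f2 <- 0
  for (v in x) {
    if (v > 0) s <- s + 1
    if (v == 1) f1 <- f1 + 1
    if (v == 2) f2 <- f2 + 1
  }
  s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

oracle_bray_curtis <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- 0; den <- 0
    for (k in seq_len(ncol(m))) {
      num <- num + abs(m[i, k] - m[j, k])
      den <- den + m[i, k] + m[j, k]
    }
    d[i, j] <- num / den
  }
  d
}

# average ranks computed by hand (midrank of tied values)
oracle_midranks <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x)) r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  r
}

oracle_spearman <- function(x, y) {
  rx <- oracle_midranks(x); ry <- oracle_midranks(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(0)
    for (j in i:m) vals <- c(vals, p[ord[j]] * m / j)
    adj[ord[i]] <- min(1, min(vals))
  }
  adj
}

# ---- graph oracles on adjacency matrices (0/1, symmetric, no loops) ----

oracle_modularity <- function(adj, mem) {
  m <- sum(adj) / 2
  if (m == 0) return(0)
  q <- 0
  for (s in unique(mem)) {
    idx <- which(mem == s)
    l_s <- sum(adj[idx, idx, drop = FALSE]) / 2
    d_s <- sum(adj[idx, , drop = FALSE])
    q <- q + l_s / m - (d_s / (2 * m))^2
  }
  q
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) { out[i] <- 0; next }
    links <- sum(adj[nb, nb]) / 2
    out[i] <- links / (k * (k - 1) / 2)
  }
  out
}

# all-pairs shortest paths by Floyd-Warshall
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# number of shortest paths between every pair, by BFS layering DP
oracle_path_counts <- function(adj, d) {
  n <- nrow(adj)
  cnt <- matrix(0, n, n)
  for (s in seq_len(n)) {
    cnt[s, s] <- 1
    for (len in 1:n) {
      for (t in which(d[s, ] == len)) {
        preds <- which(adj[t, ] > 0 & d[s, ] == len - 1)
        cnt[s, t] <- sum(cnt[s, preds])
      }
    }
  }
  cnt
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  cnt <- oracle_path_counts(adj, d)
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(d[s, t])) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t]) {
        btw[v] <- btw[v] + cnt[s, v] * cnt[v, t] / cnt[s, t]
      }
    }
  }
  btw
}

oracle_closeness <- function(adj) {
  d <- oracle_distances(adj)
  n <- nrow(adj)
  out <- numeric(n)
  for (i in seq_len(n)) {
    reach <- which(is.finite(d[i, ]) & seq_len(n) != i)
    out[i] <- if (length(reach) == 0) 0 else length(reach) / sum(d[i, reach])
  }
  out
}

oracle_avg_path <- function(adj) {
  d <- oracle_distances(adj)
  off <- d[row(d) != col(d)]
  off <- off[is.finite(off)]
  if (length(off) == 0) 0 else mean(off)
}

oracle_zi_pi <- function(adj, mem) {
  n <- nrow(adj)
  kappa <- numeric(n); pi_v <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    kappa[i] <- sum(mem[nb] == mem[i])
    ki <- length(nb)
    if (ki == 0) { pi_v[i] <- 0; next }
    acc <- 0
    for (s in unique(mem[nb])) acc <- acc + (sum(mem[nb] == s) / ki)^2
    pi_v[i] <- 1 - acc
  }
  zi <- numeric(n)
  for (s in unique(mem)) {
    idx <- which(mem == s)
    mu <- mean(kappa[idx])
    sdev <- if (length(idx) > 1) sqrt(sum((kappa[idx] - mu)^2) / (length(idx) - 1)) else 0
    zi[idx] <- if (sdev > 0) (kappa[idx] - mu) / sdev else 0
  }
  list(zi = zi, pi = pi_v, kappa = kappa)
}

# random undirected simple graph as an adjacency matrix + igraph twin
random_graph_fixture <- function(n, p_edge = 0.35) {
  adj <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (runif(1) < p_edge) adj[i, j] <- adj[j, i] <- 1
  names <- sprintf("n%02d", seq_len(n))
  dimnames(adj) <- list(names, names)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  list(adj = adj, graph = g, names = names)
}
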