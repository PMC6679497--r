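# Brute-force oracles, igraph-free: BFS shortest paths with path counting,
# pair-summed betweenness, Wasserman-Faust closeness from the BFS distance
# matrix, dense power-iteration PageRank, and a direct-sum evaluation of the
# target-network score. Used to cross-check the implementation on small
# random graphs.

# BFS from every source: distance matrix D and shortest-path counts sigma.
oracle_apsp <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    sig <- rep(0, n); sig[s] <- 1
    frontier <- s
    while (length(frontier) > 0L) {
      nxt <- integer()
      for (v in frontier) {
        for (w in which(adj[v, ] == 1)) {
          if (is.infinite(dist[w])) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1) sig[w] <- sig[w] + sig[v]
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
    sigma[s, ] <- sig
  }
  list(D = D, sigma = sigma)
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  ap <- oracle_apsp(adj)
  bet <- rep(0, n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s < t && s != v && t != v && is.finite(ap$D[s, t]) &&
            ap$D[s, v] + ap$D[v, t] == ap$D[s, t]) {
          bet[v] <- bet[v] + ap$sigma[s, v] * ap$sigma[v, t] / ap$sigma[s, t]
        }
      }
    }
  }
  denom <- (n - 1) * (n - 2) / 2
  if (denom > 0) bet / denom else bet
}

oracle_closeness <- function(adj) {
  n <- nrow(adj)
  D <- oracle_apsp(adj)$D
  vapply(seq_len(n), function(i) {
    di <- D[i, -i]
    reach <- di[is.finite(di)]
    r <- length(reach)
    if (r == 0L || sum(reach) == 0) return(0)
    (r / (n - 1)) * (r / sum(reach))
  }, numeric(1))
}

oracle_pagerank <- function(adj, damping = 0.85, tol = 1e-12, max_iter = 10000) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  v <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    v_new <- rep((1 - damping) / n, n)
    for (j in seq_len(n)) {
      if (deg[j] > 0) {
        nb <- which(adj[j, ] == 1)
        v_new[nb] <- v_new[nb] + damping * v[j] / deg[j]
      } else {
        v_new <- v_new + damping * v[j] / n # dangling: uniform
      }
    }
    if (max(abs(v_new - v)) < tol) return(v_new)
    v <- v_new
  }
  v
}

# Direct-sum target-network score using oracle BFS distances.
oracle_s_tnetwork <- function(ta, tb, adj, node_names, cs_values) {
  D <- oracle_apsp(adj)$D
  idx <- function(x) match(x, node_names)
  ta <- intersect(ta, node_names)
  tb <- intersect(tb, node_names)
  m <- length(ta)
  n <- length(tb)
  half <- function(from, to, scale2) {
    num <- 0
    den <- 0
    for (t in from) {
      w <- cs_values[t]
      d <- min(D[idx(t), idx(to)])
      num <- num + w * (if (is.infinite(d)) 0 else exp(-d / scale2))
      den <- den + w
    }
    num / den
  }
  unname(half(ta, tb, n^2) + half(tb, ta, m^2))
}

# Random test graph: symmetric adjacency with no isolated nodes (isolates are
# chained to node 1 so PageRank has no dangling states).
rand_adj <- function(n, p = 0.35) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
    }
  }
  for (i in which(rowSums(adj) == 0)) {
    j <- if (i == 1L) 2L else 1L
    adj[i, j] <- adj[j, i] <- 1L
  }
  adj
}

adj_to_graph <- function(adj, names = sprintf("N%02d", seq_len(nrow(adj)))) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- names
  g
}

path_graph <- function(nodes = c("A", "B", "C", "D", "E")) {
  n <- length(nodes)
  igraph::graph_from_edgelist(cbind(nodes[-n], nodes[-1]), directed = FALSE)
}

# Small corpus used across GO tests: p(root)=1, p(mid)=1/2, p(X)=1/4, p(Y)=1/8
toy_corpus <- function() {
  obo <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: T:0001", "name: root", "",
    "[Term]", "id: T:0002", "name: mid", "is_a: T:0001", "",
    "[Term]", "id: T:0003", "name: leaf-x", "is_a: T:0002", "",
    "[Term]", "id: T:0004", "name: leaf-y", "is_a: T:0002", ""
  ), obo)
  ont <- parse_obo(obo)
  ann <- data.frame(
    gene_id = c("B", "GX1", "D", "GX2", "GX3", "GX4", "GX5", "GX6"),
    term_id = c("T:0003", "T:0003", "T:0004", "T:0002",
                "T:0001", "T:0001", "T:0001", "T:0001"),
    stringsAsFactors = FALSE
  )
  build_go_corpus(ont, ann)
}

# Random target-set fixture on a random graph, for bound/symmetry suites.
rand_score_fixture <- function(n = 8, p = 0.4) {
  adj <- rand_adj(n, p)
  g <- adj_to_graph(adj)
  cs <- compute_centralities(g)
  nodes <- igraph::V(g)$name
  ta <- sample(nodes, sample(1:3, 1))
  tb <- sample(nodes, sample(1:3, 1))
  list(g = g, cs = cs, ta = ta, tb = tb)
}

expect_ss_error <- function(expr, code) {
  testthat::expect_error(expr, class = paste0("synscreen_error_", code))
}

expect_ss_warning <- function(expr, code) {
  testthat::expect_warning(expr, class = paste0("synscreen_warning_", code))
}
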