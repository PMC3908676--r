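# Graph builders and naive reference oracles used across the test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

named_graph <- function(...) {
  # named_graph("a","b", "b","c") builds the graph with edges (a,b),(b,c)
  ends <- c(...)
  g <- igraph::graph_from_edgelist(
    matrix(ends, ncol = 2, byrow = TRUE), directed = FALSE)
  g
}

complete_named <- function(n, ids = sprintf("n%02d", seq_len(n))) {
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- ids
  g
}

star_named <- function(k) {
  # centre "c0" plus k leaves
  g <- igraph::make_star(k + 1, mode = "undirected", center = 1)
  igraph::V(g)$name <- c("c0", sprintf("l%02d", seq_len(k)))
  g
}

random_named_graph <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

# Naive cluster-node distance: materializes the common-neighbour set and
# counts every edge by explicit double loops over the edge list, following
# the definition category by category. Deliberately slow and independent of
# the package's set-arithmetic implementation.
oracle_distance <- function(net, K, v) {
  em <- igraph::as_edgelist(net)
  nodes <- igraph::V(net)$name
  adjacent <- function(x, y) {
    any((em[, 1] == x & em[, 2] == y) | (em[, 1] == y & em[, 2] == x))
  }
  m <- 0L
  for (k in K) if (adjacent(v, k)) m <- m + 1L
  cn <- character(0)
  for (u in nodes) {
    if (u %in% K || u == v) next
    if (!adjacent(u, v)) next
    for (k in K) {
      if (adjacent(u, k)) {
        cn <- c(cn, u)
        break
      }
    }
  }
  deg_k <- 0L; out_k <- 0L; deg_v <- 0L; out_v <- 0L
  for (i in seq_len(nrow(em))) {
    a <- em[i, 1]; b <- em[i, 2]
    a_in <- a %in% K; b_in <- b %in% K
    if (xor(a_in, b_in)) {
      deg_k <- deg_k + 1L
      outside <- if (a_in) b else a
      if (outside != v && !(outside %in% cn)) out_k <- out_k + 1L
    }
    if (a == v || b == v) {
      deg_v <- deg_v + 1L
      other <- if (a == v) b else a
      if (!(other %in% K) && !(other %in% cn)) out_v <- out_v + 1L
    }
  }
  list(size_K = length(K), m = m, deg_K = deg_k, deg_v = deg_v,
       out_K = out_k, out_v = out_v,
       d = (length(K) - m) / length(K) +
         (out_k + out_v) / (deg_k + deg_v - 2 * m + length(K)))
}

# Naive precision/recall by brute-force double-loop matching.
oracle_evaluate <- function(P, B, omega = 0.2) {
  n_cp <- 0L
  for (p in P) {
    for (b in B) {
      if (neighbour_affinity(p, b) >= omega) {
        n_cp <- n_cp + 1L
        break
      }
    }
  }
  n_cb <- 0L
  for (b in B) {
    for (p in P) {
      if (neighbour_affinity(p, b) >= omega) {
        n_cb <- n_cb + 1L
        break
      }
    }
  }
  list(precision = n_cp / length(P), recall = n_cb / length(B))
}

random_complex_set <- function(n, universe, max_size = 6) {
  complex_set(lapply(seq_len(n), function(i) {
    sample(universe, sample(2:max_size, 1))
  }))
}
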