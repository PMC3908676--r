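# Scoring primitives: Jaccard edge weight, pruned-neighbourhood node weight,
# modified Czekanovski-Dice cluster-node distance, robustness degree, and
# neighbour affinity. These are the quantities the detector optimises.

check_vertex <- function(net, v) {
  if (!v %in% igraph::V(net)$name) {
    stop_noncall("unknown node: ", v)
  }
}

nbr_names <- function(net, v) {
  names(igraph::neighbors(net, v))
}

#' Jaccard edge weight
#'
#' The weight of an edge (u, v) is the Jaccard coefficient of the two
#' endpoints' neighbourhoods: `|Γ(u) ∩ Γ(v)| / |Γ(u) ∪ Γ(v)|`. Since u and v
#' are adjacent, u ∈ Γ(v) and v ∈ Γ(u), so the union is never empty and the
#' weight lies in [0, 1). A weight of 0 means the endpoints share no
#' neighbours — in a PPI network such interactions are considered
#' unreliable and are dropped during detector initialization.
#'
#' @param net An undirected simple [igraph::igraph] with named vertices.
#' @param u,v Names of two adjacent vertices.
#' @return The edge weight in `[0, 1]`.
#' @examples
#' k3 <- igraph::make_full_graph(3)
#' igraph::V(k3)$name <- c("a", "b", "c")
#' edge_weight(k3, "a", "b") # 1/3
#' @export
edge_weight <- function(net, u, v) {
  check_vertex(net, u)
  check_vertex(net, v)
  gu <- nbr_names(net, u)
  gv <- nbr_names(net, v)
  if (!v %in% gu) {
    stop_noncall("edge weight is only defined on edges; (", u, ", ", v,
                 ") is not an edge")
  }
  length(intersect(gu, gv)) / length(union(gu, gv))
}

#' Pruned neighbourhood graph of a node
#'
#' The neighbourhood graph G_v of a node v consists of v, all its
#' neighbours, and the edges among them. Nodes of degree 1 within G_v
#' (those attached to nothing but one other node — topologically unreliable
#' interactions) are removed in a single simultaneous pass, together with
#' their incident edges; v itself is removed when its G_v degree is 1. The
#' remainder G_v' is returned.
#'
#' @param net An undirected simple [igraph::igraph] with named vertices.
#' @param v Vertex name.
#' @return A list of class `neighbourhood_graph` with elements `centre`,
#'   `retained_nodes` (character), `retained_edges` (two-column character
#'   matrix), and `graph` (the induced [igraph::igraph] on the retained
#'   nodes).
#' @export
neighbourhood_graph <- function(net, v) {
  check_vertex(net, v)
  nodes <- c(v, nbr_names(net, v))
  gv <- igraph::induced_subgraph(net, nodes)
  deg <- igraph::degree(gv)
  gvp <- igraph::delete_vertices(gv, names(deg)[deg == 1])
  em <- igraph::as_edgelist(gvp)
  structure(
    list(centre = v,
         retained_nodes = lex_sort(igraph::V(gvp)$name),
         retained_edges = em,
         graph = gvp),
    class = "neighbourhood_graph"
  )
}

#' @export
print.neighbourhood_graph <- function(x, ...) {
  cat("neighbourhood graph of", x$centre, ":",
      length(x$retained_nodes), "nodes,", nrow(x$retained_edges),
      "edges after degree-1 pruning\n")
  invisible(x)
}

#' Node weight
#'
#' The weight of a node v is the average degree of the nodes in its pruned
#' neighbourhood graph G_v' (see [neighbourhood_graph()]), i.e.
#' `2 * |E'| / |V''|`, and 0 when G_v' is empty. A high node weight marks a
#' node sitting in a densely connected region — the property wanted of a
#' cluster seed.
#'
#' @param net An undirected simple [igraph::igraph] with named vertices.
#' @param v Vertex name.
#' @return Non-negative node weight (average-degree units).
#' @export
node_weight <- function(net, v) {
  ng <- neighbourhood_graph(net, v)
  nv <- length(ng$retained_nodes)
  if (nv == 0) return(0)
  2 * nrow(ng$retained_edges) / nv
}

#' Node weights for all (or selected) vertices
#'
#' @param net An undirected simple [igraph::igraph] with named vertices.
#' @param vs Vertex names; defaults to all vertices.
#' @return Named numeric vector of node weights.
#' @export
node_weights <- function(net, vs = igraph::V(net)$name) {
  vapply(stats::setNames(vs, vs), function(v) node_weight(net, v), numeric(1))
}

#' Distance between a cluster and a neighbouring node
#'
#' A modified Czekanovski-Dice distance between a cluster K and an outside
#' node v, combining the direct connections between v and K with the
#' indirect evidence carried by their common neighbours:
#'
#' `d(v, K) = (|K| - m)/|K| + (OUT(K) + OUT(v)) / (deg(K) + deg(v) - 2m + |K|)`
#'
#' where m is the number of edges between v and members of K, deg(K) the
#' total external degree of K (edges with exactly one endpoint in K),
#' deg(v) the degree of v, and OUT(K), OUT(v) count the external edges of K
#' resp. v that reach nodes which are neither in K, nor v itself, nor
#' common neighbours of K and v. Smaller distance means higher priority for
#' absorption into K.
#'
#' @param net An undirected simple [igraph::igraph] with named vertices.
#' @param K Character vector of cluster member names (non-empty, v not
#'   among them).
#' @param v Candidate vertex name.
#' @return A list of class `distance_breakdown` with the counts `size_K`,
#'   `m`, `deg_K`, `deg_v`, `out_K`, `out_v` and the distance `d`.
#' @export
cluster_node_distance <- function(net, K, v) {
  K <- unique(as.character(K))
  if (length(K) == 0) stop_noncall("cluster K must be non-empty")
  if (v %in% K) stop_noncall("node ", v, " is a member of K")
  check_vertex(net, v)
  for (k in K) check_vertex(net, k)

  gv <- nbr_names(net, v)
  adj_k <- lapply(stats::setNames(K, K), function(k) nbr_names(net, k))
  boundary <- setdiff(unique(unlist(adj_k, use.names = FALSE)), K)
  m <- length(intersect(gv, K))
  cn <- setdiff(intersect(gv, boundary), v)
  excluded_k <- c(K, v, cn)
  deg_k <- sum(vapply(adj_k, function(nb) length(setdiff(nb, K)), numeric(1)))
  out_k <- sum(vapply(adj_k, function(nb) length(setdiff(nb, excluded_k)),
                      numeric(1)))
  deg_v <- length(gv)
  out_v <- length(setdiff(gv, c(K, cn)))
  denom <- deg_k + deg_v - 2 * m + length(K)
  if (denom <= 0) {
    stop_noncall("node ", v, " is not a neighbour of K (degenerate distance)")
  }
  structure(
    list(size_K = length(K), m = m, deg_K = deg_k, deg_v = deg_v,
         out_K = out_k, out_v = out_v,
         d = (length(K) - m) / length(K) + (out_k + out_v) / denom),
    class = "distance_breakdown"
  )
}

#' @export
print.distance_breakdown <- function(x, ...) {
  cat(sprintf(
    "d(v, K) = %.4f  (|K|=%d, m=%d, deg(K)=%d, deg(v)=%d, OUT(K)=%d, OUT(v)=%d)\n",
    x$d, x$size_K, x$m, x$deg_K, x$deg_v, x$out_K, x$out_v))
  invisible(x)
}

#' Robustness degree of a cluster
#'
#' Iteratively removes the node of highest current degree (ties broken by
#' the lexicographically smallest ID) from the subgraph induced by the
#' cluster, until the remainder is disconnected or empty. The robustness
#' degree is the fraction of the original members removed: a clique
#' tolerates the removal of every node (R = 1), while a star collapses
#' after one (R = 1/(k+1)). Clusters with many alternative internal paths —
#' the topological signature of a reliable protein complex — score high.
#'
#' @param net An undirected simple [igraph::igraph] with named vertices.
#' @param members Non-empty character vector of member names; the induced
#'   subgraph must be connected.
#' @return A list of class `robustness_result` with `n_removed`,
#'   `initial_size` and the ratio `R = n_removed / initial_size`.
#' @examples
#' k4 <- igraph::make_full_graph(4)
#' igraph::V(k4)$name <- letters[1:4]
#' robustness(k4, letters[1:4])$R # 1
#' @export
robustness <- function(net, members) {
  members <- unique(as.character(members))
  if (length(members) == 0) stop_noncall("cluster must be non-empty")
  for (v in members) check_vertex(net, v)
  sub <- igraph::induced_subgraph(net, members)
  if (!igraph::is_connected(sub)) {
    stop_noncall("robustness is only defined for connected clusters")
  }
  n_removed <- 0L
  repeat {
    deg <- igraph::degree(sub)
    top <- names(deg)[deg == max(deg)]
    sub <- igraph::delete_vertices(sub, lex_min(top))
    n_removed <- n_removed + 1L
    if (igraph::vcount(sub) == 0 || !igraph::is_connected(sub)) break
  }
  structure(
    list(n_removed = n_removed, initial_size = length(members),
         R = n_removed / length(members)),
    class = "robustness_result"
  )
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf("robustness R = %d/%d = %.4f\n",
              x$n_removed, x$initial_size, x$R))
  invisible(x)
}

#' Neighbour affinity of two node sets
#'
#' `NA(A, B) = |A ∩ B|^2 / (|A| * |B|)`, the overlap measure used both to
#' merge near-duplicate clusters during detection and to match predicted
#' complexes against reference complexes during evaluation. It is 1 exactly
#' when the two sets are equal and 0 when they are disjoint.
#'
#' @param A,B Non-empty character vectors of node IDs (duplicates ignored).
#' @return Affinity in `[0, 1]`.
#' @examples
#' neighbour_affinity(c("a", "b"), c("b", "c")) # 0.25
#' @export
neighbour_affinity <- function(A, B) {
  A <- unique(as.character(A))
  B <- unique(as.character(B))
  if (length(A) == 0 || length(B) == 0) {
    stop_noncall("neighbour affinity requires two non-empty sets")
  }
  length(intersect(A, B))^2 / (length(A) * length(B))
}
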