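# The detection pipeline: initialization (Jaccard weighting + zero-weight
# edge removal), seed selection by node weight, greedy cluster expansion
# constrained by robustness and minimum edge weight, and neighbour-affinity
# post-merging.

#' Detection parameters
#'
#' @param theta Minimum robustness degree a cluster must keep while growing,
#'   in `[0, 1]`. Higher values demand clusters that survive more
#'   highest-degree node removals before disconnecting.
#' @param gamma Minimum Jaccard edge weight allowed inside a cluster, in
#'   `[0, 1]`. Higher values demand that every retained interaction is
#'   supported by shared neighbours.
#' @param min_size Minimum number of members for a cluster to be reported
#'   (smaller clusters are still generated and mark their members visited,
#'   they are just not printed).
#' @param merge_threshold Neighbour-affinity cutoff at or above which a new
#'   cluster is merged into its closest existing cluster instead of being
#'   added separately.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(theta = 0.5, gamma = 0.1, min_size = 3,
                             merge_threshold = 0.5) {
  stopifnot(is.numeric(theta), length(theta) == 1, theta >= 0, theta <= 1)
  stopifnot(is.numeric(gamma), length(gamma) == 1, gamma >= 0, gamma <= 1)
  stopifnot(is.numeric(min_size), length(min_size) == 1, min_size >= 1)
  stopifnot(is.numeric(merge_threshold), length(merge_threshold) == 1,
            merge_threshold > 0, merge_threshold <= 1)
  structure(list(theta = theta, gamma = gamma,
                 min_size = as.integer(min_size),
                 merge_threshold = merge_threshold),
            class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  cat(sprintf(
    "detection params: theta=%.3g gamma=%.3g min_size=%d merge_threshold=%.3g\n",
    x$theta, x$gamma, x$min_size, x$merge_threshold))
  invisible(x)
}

#' Read detection parameters from a config file
#'
#' Accepts either YAML (`theta: 0.5`) or plain `key = value` lines. Only
#' the keys `theta`, `gamma`, `min_size` and `merge_threshold` are used;
#' missing keys keep their defaults.
#'
#' @param path Path to the config file.
#' @return A [detection_params()] object.
#' @export
read_detection_config <- function(path) {
  if (!file.exists(path)) stop_noncall("config file not found: ", path)
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) NULL)
  if (!is.list(cfg)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[grepl("=", lines, fixed = TRUE)]
    kv <- strsplit(lines, "=", fixed = TRUE)
    cfg <- stats::setNames(
      lapply(kv, function(x) as.numeric(trimws(x[[2]]))),
      vapply(kv, function(x) trimws(x[[1]]), character(1)))
  }
  known <- intersect(names(cfg), c("theta", "gamma", "min_size",
                                   "merge_threshold"))
  do.call(detection_params, cfg[known])
}

# Jaccard weight for every edge, computed on the raw input graph.
edge_weights_all <- function(net, adj) {
  if (igraph::ecount(net) == 0) return(numeric(0))
  em <- igraph::as_edgelist(net)
  vapply(seq_len(nrow(em)), function(i) {
    gu <- adj[[em[i, 1]]]
    gv <- adj[[em[i, 2]]]
    length(intersect(gu, gv)) / length(union(gu, gv))
  }, numeric(1))
}

adj_names <- function(net) {
  al <- lapply(igraph::as_adj_list(net), names)
  names(al) <- igraph::V(net)$name
  al
}

#' Initialize a network for detection
#'
#' Computes the Jaccard weight of every edge of the input graph, then
#' deletes all zero-weight edges (interactions whose endpoints share no
#' neighbour, which are considered unreliable). Weights are computed once,
#' on the raw graph; they are not recomputed after the deletion. Vertices
#' left without edges remain in the graph as isolated nodes.
#'
#' @param net An undirected simple [igraph::igraph] with named vertices.
#' @return The filtered graph with a `weight` edge attribute.
#' @export
initialize_network <- function(net) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::ecount(net) == 0) {
    return(net)
  }
  w <- edge_weights_all(net, adj_names(net))
  igraph::E(net)$weight <- w
  igraph::delete_edges(net, igraph::E(net)[w == 0])
}

#' Select the next seed node
#'
#' Among the unvisited nodes of the filtered network, returns the one with
#' the highest node weight (ties broken by lexicographically smallest ID).
#' Returns `NULL` — the termination signal — when every node has been
#' visited, or when the best remaining node weight is 0 (all remaining
#' nodes are isolated or sit in pruned-away neighbourhoods).
#'
#' @param wnet Filtered network from [initialize_network()].
#' @param visited Named logical vector over the vertices of `wnet`.
#' @param weights Optional precomputed [node_weights()] for `wnet`.
#' @return A vertex name, or `NULL` to signal termination.
#' @export
select_seed <- function(wnet, visited, weights = NULL) {
  unvisited <- names(visited)[!visited]
  if (length(unvisited) == 0) return(NULL)
  if (is.null(weights)) weights <- node_weights(wnet, unvisited)
  w <- weights[unvisited]
  if (max(w) <= 0) return(NULL)
  lex_min(unvisited[w == max(w)])
}

# Minimum stored edge weight over the subgraph induced by `members`
# (Inf when the induced subgraph has no edges).
cluster_min_edge_weight <- function(wnet, members) {
  sub <- igraph::induced_subgraph(wnet, members)
  if (igraph::ecount(sub) == 0) return(Inf)
  min(igraph::E(sub)$weight)
}

#' Grow a cluster from a seed
#'
#' Starting from `K = {seed}`, repeatedly considers the frontier N_K of
#' non-member, non-rejected nodes adjacent to the cluster, takes the
#' candidate minimizing the cluster-node distance d(v, K) (ties broken
#' lexicographically), and admits it only if the enlarged cluster keeps
#' robustness degree at least `theta` and minimum internal edge weight at
#' least `gamma`. A failing candidate is permanently rejected for this
#' cluster. Expansion stops when the frontier is exhausted.
#'
#' @param wnet Filtered network from [initialize_network()].
#' @param seed Seed vertex name.
#' @param params A [detection_params()] object.
#' @return A list of class `ppi_cluster` with `members` (character vector,
#'   seed first, then in order of admission) and `seed`.
#' @export
expand_cluster <- function(wnet, seed, params = detection_params()) {
  check_vertex(wnet, seed)
  adj <- adj_names(wnet)
  wkey <- stats::setNames(
    igraph::E(wnet)$weight %||% rep(1, igraph::ecount(wnet)),
    if (igraph::ecount(wnet) > 0) {
      em <- igraph::as_edgelist(wnet)
      pair_key(em[, 1], em[, 2])
    } else character(0))
  K <- seed
  rejected <- character(0)
  cur_min <- Inf
  repeat {
    frontier <- setdiff(unique(unlist(adj[K], use.names = FALSE)),
                        c(K, rejected))
    if (length(frontier) == 0) break
    d <- vapply(frontier,
                function(v) cluster_node_distance(wnet, K, v)$d, numeric(1))
    v <- lex_min(frontier[d == min(d)])
    cand_min <- min(cur_min, wkey[pair_key(v, intersect(adj[[v]], K))])
    if (cand_min >= params$gamma &&
        robustness(wnet, c(K, v))$R >= params$theta) {
      K <- c(K, v)
      cur_min <- cand_min
    } else {
      rejected <- c(rejected, v)
    }
  }
  structure(list(members = K, seed = seed), class = "ppi_cluster")
}

#' @export
print.ppi_cluster <- function(x, ...) {
  cat("cluster of", length(x$members), "members (seed", x$seed, ")\n")
  invisible(x)
}

#' Merge a new cluster into a collection, or append it
#'
#' Finds the existing cluster with the largest neighbour affinity to `K`
#' (ties go to the earliest-inserted). If that affinity reaches
#' `merge_threshold`, the existing cluster is replaced by the union of the
#' two member sets (a single merge; the union is not re-compared against
#' the rest of the collection). Otherwise `K` is appended as an independent
#' cluster. This lets clusters share nodes while preventing near-duplicate
#' output.
#'
#' @param existing List of character vectors (each may carry attributes
#'   `merged` and `seeds`; see [detect_complexes()]).
#' @param K Character vector of new cluster members (non-empty).
#' @param merge_threshold Affinity cutoff in `(0, 1]`.
#' @return The updated list.
#' @export
merge_or_add <- function(existing, K, merge_threshold = 0.5) {
  seeds_k <- attr(K, "seeds") %||% character(0)
  K <- unique(as.character(K))
  if (length(K) == 0) stop_noncall("cannot add an empty cluster")
  if (length(existing) == 0) {
    new <- K
    attr(new, "merged") <- FALSE
    attr(new, "seeds") <- seeds_k
    return(c(existing, list(new)))
  }
  na <- vapply(existing, function(cl) neighbour_affinity(cl, K), numeric(1))
  i <- which.max(na)
  if (na[[i]] >= merge_threshold) {
    merged <- union(existing[[i]], K)
    attr(merged, "merged") <- TRUE
    attr(merged, "seeds") <- c(attr(existing[[i]], "seeds"), seeds_k)
    existing[[i]] <- merged
    existing
  } else {
    new <- K
    attr(new, "merged") <- FALSE
    attr(new, "seeds") <- seeds_k
    c(existing, list(new))
  }
}

#' Detect overlapping protein complexes
#'
#' Runs the full pipeline: the network is weighted and filtered
#' ([initialize_network()]), then clusters are grown one at a time — seed
#' selection by highest node weight ([select_seed()]), greedy expansion
#' under the robustness and edge-weight constraints ([expand_cluster()]),
#' and neighbour-affinity merging into the running collection
#' ([merge_or_add()]). All members of a finished cluster are marked
#' visited, which gates only future seeding: members of earlier clusters
#' remain eligible expansion candidates, so output clusters may overlap.
#' The loop ends when no unvisited node with positive weight remains.
#'
#' @param net An undirected simple [igraph::igraph] with named vertices,
#'   e.g. from [read_network()].
#' @param params A [detection_params()] object.
#' @param verbose Emit a per-cluster progress message.
#' @return A [complex_set()] of clusters with at least `min_size` members,
#'   in canonical order. The attribute `detection_log` holds a data frame
#'   over the full (unfiltered) collection: member count, whether the entry
#'   absorbed a merge, its seed(s), its robustness degree and minimum
#'   internal edge weight on the filtered network.
#' @examples
#' g <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
#' igraph::V(g)$name <- letters[1:8]
#' detect_complexes(g)
#' @export
detect_complexes <- function(net, params = detection_params(),
                             verbose = FALSE) {
  stopifnot(inherits(params, "detection_params"))
  wnet <- initialize_network(net)
  vs <- igraph::V(wnet)$name
  visited <- stats::setNames(rep(FALSE, length(vs)), vs)
  weights <- if (length(vs) > 0) node_weights(wnet) else numeric(0)
  clusters <- list()
  repeat {
    seed <- select_seed(wnet, visited, weights)
    if (is.null(seed)) break
    visited[seed] <- TRUE
    cl <- expand_cluster(wnet, seed, params)
    visited[cl$members] <- TRUE
    members <- cl$members
    attr(members, "seeds") <- seed
    n_before <- length(clusters)
    clusters <- merge_or_add(clusters, members, params$merge_threshold)
    if (verbose) {
      message(sprintf(
        "seed %s -> cluster of %d member(s), R=%.3f, min w=%.3f, %s",
        seed, length(cl$members),
        robustness(wnet, cl$members)$R,
        cluster_min_edge_weight(wnet, cl$members),
        if (length(clusters) > n_before) "appended" else "merged"))
    }
  }
  log <- data.frame(
    size = vapply(clusters, length, integer(1)),
    merged = vapply(clusters, function(cl) isTRUE(attr(cl, "merged")),
                    logical(1)),
    seeds = vapply(clusters, function(cl) {
      paste(attr(cl, "seeds"), collapse = ",")
    }, character(1)),
    robustness = vapply(clusters, function(cl) {
      tryCatch(robustness(wnet, cl)$R, error = function(e) NA_real_)
    }, numeric(1)),
    min_edge_weight = vapply(clusters, function(cl) {
      cluster_min_edge_weight(wnet, cl)
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  kept <- clusters[lengths(clusters) >= params$min_size]
  cs <- canonicalize_complexes(
    complex_set(lapply(kept, function(x) as.character(x))))
  attr(cs, "detection_log") <- log
  cs
}
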