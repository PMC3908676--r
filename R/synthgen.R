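# Planted-complex network generator. Emulates the structure the detector
# assumes of real PPI data: locally dense regions (planted complexes)
# embedded in a sparse noisy background, optionally sharing nodes so that
# ground truth is genuinely overlapping.

#' Configuration for the planted-complex generator
#'
#' @param n_complexes Number of planted complexes.
#' @param size_min,size_max Complex size range (uniform); `size_min >= 3`.
#' @param p_within Probability of an edge between each pair of proteins
#'   inside a complex.
#' @param overlap_fraction Fraction of consecutive complexes that share
#'   exactly one protein with their predecessor, in `[0, 1)`.
#' @param n_background Number of extra background proteins outside every
#'   complex.
#' @param p_background Probability of an edge for every cross pair — any
#'   pair of proteins not inside a common complex (background-background,
#'   background-complex and between-complex pairs).
#' @param rng_seed Integer seed; the generated network is a pure function
#'   of the configuration including this seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_complexes = 5, size_min = 5, size_max = 5,
                             p_within = 0.9, overlap_fraction = 0,
                             n_background = 20, p_background = 0.01,
                             rng_seed = 1) {
  stopifnot(is.numeric(n_complexes), n_complexes >= 0)
  if (!is.numeric(size_min) || size_min < 3) {
    stop_noncall("size_min must be at least 3 (a complex needs >= 3 proteins)")
  }
  stopifnot(is.numeric(size_max), size_max >= size_min)
  stopifnot(p_within >= 0, p_within <= 1)
  stopifnot(overlap_fraction >= 0, overlap_fraction < 1)
  stopifnot(is.numeric(n_background), n_background >= 0)
  stopifnot(p_background >= 0, p_background <= 1)
  structure(list(n_complexes = as.integer(n_complexes),
                 size_min = as.integer(size_min),
                 size_max = as.integer(size_max),
                 p_within = p_within,
                 overlap_fraction = overlap_fraction,
                 n_background = as.integer(n_background),
                 p_background = p_background,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_config")
}

sample_connected_edges <- function(members, p_within, max_tries = 10000L) {
  if (length(members) < 2) return(matrix(character(0), ncol = 2))
  pairs <- utils::combn(members, 2)
  for (i in seq_len(max_tries)) {
    keep <- stats::runif(ncol(pairs)) < p_within
    if (!any(keep)) next
    g <- igraph::graph_from_edgelist(t(pairs[, keep, drop = FALSE]),
                                     directed = FALSE)
    if (igraph::vcount(g) == length(members) && igraph::is_connected(g)) {
      return(t(pairs[, keep, drop = FALSE]))
    }
  }
  stop_noncall("could not sample a connected complex after ", max_tries,
               " tries; p_within is too low for the requested size")
}

#' Generate a planted-complex PPI network with ground truth
#'
#' Creates `n_complexes` dense groups (each internal pair joined with
#' probability `p_within`, re-sampled until the group is internally
#' connected), lets the first `round(overlap_fraction * (n_complexes - 1))`
#' consecutive pairs of complexes share exactly one protein, adds
#' `n_background` background proteins, and joins every cross pair with
#' probability `p_background`. Fully reproducible from `rng_seed`: the
#' caller's RNG state is left untouched.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `network` (an [igraph::igraph]; background proteins
#'   that received no edge remain as isolated vertices) and `truth` (the
#'   planted [complex_set()]).
#' @examples
#' out <- generate_planted_network(synthetic_config(
#'   n_complexes = 3, p_within = 1, n_background = 0, p_background = 0))
#' length(out$truth) # 3
#' @export
generate_planted_network <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$rng_seed, {
    complexes <- list()
    edges <- matrix(character(0), ncol = 2)
    n_shared <- if (cfg$n_complexes > 1) {
      as.integer(round(cfg$overlap_fraction * (cfg$n_complexes - 1)))
    } else 0L
    shared_used <- character(0)
    for (i in seq_len(cfg$n_complexes)) {
      size <- cfg$size_min +
        sample.int(cfg$size_max - cfg$size_min + 1L, 1L) - 1L
      members <- sprintf("C%02d.%02d", i, seq_len(size))
      if (i >= 2 && (i - 1) <= n_shared) {
        # share one predecessor member; prefer one that is not already a
        # shared node so consecutive overlaps stay pairwise
        pool <- setdiff(complexes[[i - 1]], shared_used)
        if (length(pool) == 0) pool <- complexes[[i - 1]]
        shared <- pool[sample.int(length(pool), 1L)]
        shared_used <- c(shared_used, shared)
        members[1] <- shared
      }
      complexes[[i]] <- members
      edges <- rbind(edges, sample_connected_edges(members, cfg$p_within))
    }
    background <- if (cfg$n_background > 0) {
      sprintf("B%02d", seq_len(cfg$n_background))
    } else character(0)
    nodes <- lex_sort(unique(c(unlist(complexes), background)))
    # cross pairs: every unordered pair not internal to some complex
    if (length(nodes) > 1 && cfg$p_background > 0) {
      internal <- unlist(lapply(complexes, function(m) {
        if (length(m) < 2) return(character(0))
        p <- utils::combn(lex_sort(m), 2)
        pair_key(p[1, ], p[2, ])
      }))
      all_pairs <- utils::combn(nodes, 2)
      keys <- pair_key(all_pairs[1, ], all_pairs[2, ])
      cross <- !(keys %in% internal)
      keep <- cross & stats::runif(length(keys)) < cfg$p_background
      edges <- rbind(edges, t(all_pairs[, keep, drop = FALSE]))
    }
    g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
    igraph::V(g)$name <- nodes
    if (nrow(edges) > 0) {
      keys <- pair_key(edges[, 1], edges[, 2])
      edges <- edges[!duplicated(keys), , drop = FALSE]
      g <- igraph::add_edges(g, t(edges))
    }
    list(network = g,
         truth = complex_set(complexes))
  })
}
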