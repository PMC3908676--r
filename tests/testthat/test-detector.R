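test_that("initialization weights edges once and removes zero-weight ones", {
  st <- star_named(4)
  w <- initialize_network(st)
  expect_equal(igraph::ecount(w), 0)
  expect_equal(igraph::vcount(w), 5) # nodes survive as isolated

  tri <- complete_named(3, c("a", "b", "c"))
  wt <- initialize_network(tri)
  expect_equal(igraph::ecount(wt), 3)
  expect_equal(igraph::E(wt)$weight, rep(1 / 3, 3))

  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_equal(igraph::vcount(initialize_network(empty)), 0)
})

test_that("seed selection honours visited state and zero weights", {
  k4_iso <- igraph::add_vertices(complete_named(4, c("b", "c", "d", "e")), 1,
                                 name = "a")
  w <- initialize_network(k4_iso)
  visited <- stats::setNames(rep(FALSE, 5), igraph::V(w)$name)

  # lexicographically smallest K4 member wins; the isolated "a" has weight 0
  expect_identical(select_seed(w, visited), "b")

  visited[] <- TRUE
  expect_null(select_seed(w, visited))

  iso <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(iso)$name <- c("x", "y", "z")
  vis <- stats::setNames(rep(FALSE, 3), c("x", "y", "z"))
  expect_null(select_seed(iso, vis))
})

test_that("expansion grows a clique fully and respects gamma", {
  k4 <- complete_named(4, letters[1:4])
  w <- initialize_network(k4)

  cl <- expand_cluster(w, "a", detection_params(theta = 0.5, gamma = 0.2))
  expect_setequal(cl$members, letters[1:4])

  tight <- expand_cluster(w, "a", detection_params(theta = 0.5, gamma = 0.9))
  expect_identical(tight$members, "a")

  lone <- initialize_network(star_named(3))
  expect_identical(expand_cluster(lone, "c0", detection_params())$members,
                   "c0")
  expect_error(expand_cluster(w, "nope", detection_params()),
               "unknown node")
})

test_that("merge_or_add merges at the affinity threshold and appends below", {
  expect_equal(merge_or_add(list(), c("a", "b"))[[1]],
               c("a", "b"), ignore_attr = TRUE)

  existing <- merge_or_add(list(), c("c", "d"))
  # identical cluster: NA = 1 -> merged, membership unchanged
  merged <- merge_or_add(existing, c("c", "d"))
  expect_length(merged, 1)
  expect_setequal(merged[[1]], c("c", "d"))
  expect_true(attr(merged[[1]], "merged"))

  # disjoint cluster: NA = 0 -> appended
  appended <- merge_or_add(existing, c("a", "b"))
  expect_length(appended, 2)
  expect_setequal(appended[[2]], c("a", "b"))
  expect_false(attr(appended[[2]], "merged"))

  # overlap {a,b,c} vs {b,c,d}: NA = 4/9 < 0.5 -> appended;
  # {a,b,c,d} vs {a,b,c}: NA = 9/12 >= 0.5 -> merged
  base <- merge_or_add(list(), c("a", "b", "c"))
  expect_length(merge_or_add(base, c("b", "c", "d")), 2)
  u <- merge_or_add(base, c("a", "b", "c", "d"))
  expect_length(u, 1)
  expect_setequal(u[[1]], c("a", "b", "c", "d"))
})

test_that("detection recovers two disjoint cliques exactly", {
  g <- igraph::disjoint_union(complete_named(4, letters[1:4]),
                              complete_named(4, letters[5:8]))
  cs <- detect_complexes(g, detection_params(theta = 0.5, gamma = 0.2))
  expect_length(cs, 2)
  expect_setequal(unclass(cs)[[1]], letters[1:4])
  expect_setequal(unclass(cs)[[2]], letters[5:8])
})

test_that("star and empty networks yield no complexes", {
  expect_length(detect_complexes(star_named(6)), 0)
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_length(detect_complexes(empty), 0)
})

test_that("two cliques sharing a node both keep the shared node", {
  a_side <- utils::combn(c("a", "b", "c", "d"), 2)
  b_side <- utils::combn(c("d", "e", "f", "g"), 2)
  g <- igraph::graph_from_edgelist(t(cbind(a_side, b_side)),
                                   directed = FALSE)
  cs <- detect_complexes(g)
  expect_length(cs, 2)
  members <- unclass(cs)
  expect_true(all(vapply(members, function(m) "d" %in% m, logical(1))))
  expect_setequal(union(members[[1]], members[[2]]), letters[1:7])
})

test_that("emitted clusters satisfy the size, connectivity and constraint audit", {
  withr::local_seed(21)
  params <- detection_params(theta = 0.5, gamma = 0.1, min_size = 3)
  for (i in 1:5) {
    sim <- generate_planted_network(synthetic_config(
      n_complexes = 4, size_min = 4, size_max = 7, p_within = 0.85,
      n_background = 15, p_background = 0.02, rng_seed = 100 + i))
    w <- initialize_network(sim$network)
    cs <- detect_complexes(sim$network, params)
    log <- attr(cs, "detection_log")
    for (m in unclass(cs)) {
      expect_gte(length(m), params$min_size)
      expect_true(igraph::is_connected(igraph::induced_subgraph(w, m)))
    }
    # non-merged collection entries must satisfy both growth constraints
    clean <- log[!log$merged, ]
    expect_true(all(clean$robustness >= params$theta))
    expect_true(all(clean$min_edge_weight >= params$gamma))
  }
})

test_that("detection output is byte-identical across repeated runs", {
  sim <- generate_planted_network(synthetic_config(rng_seed = 42))
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_complexes(detect_complexes(sim$network), f1)
  write_complexes(detect_complexes(sim$network), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_gt(length(readLines(f1)), 0)
})

test_that("detection params validate and load from config files", {
  expect_error(detection_params(theta = 1.5))
  expect_error(detection_params(merge_threshold = 0))
  expect_error(detection_params(min_size = 0))

  fy <- withr::local_tempfile(lines = c("theta: 0.4", "gamma: 0.15",
                                        "min_size: 4"))
  py <- read_detection_config(fy)
  expect_equal(py$theta, 0.4)
  expect_equal(py$gamma, 0.15)
  expect_equal(py$min_size, 4L)
  expect_equal(py$merge_threshold, 0.5)

  fk <- withr::local_tempfile(lines = c("theta = 0.6", "merge_threshold = 0.7"))
  pk <- read_detection_config(fk)
  expect_equal(pk$theta, 0.6)
  expect_equal(pk$merge_threshold, 0.7)
})
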