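test_that("load_network filters by confidence, converts dialects, and cleans edges", {
  tf <- write_edges_tsv(c("A\tB\t0.9", "B\tC\t0.6", "A\tC\t0.8"))
  net <- load_network(tf, score_threshold = 0.7)
  expect_equal(igraph::ecount(net), 2)
  el <- igraph::as_edgelist(net)
  keys <- apply(el, 1, function(r) paste(sort(r), collapse = "-"))
  expect_setequal(keys, c("A-B", "A-C"))

  # STRING 0-999 integer dialect
  tf2 <- write_edges_tsv(c("A\tB\t950", "B\tC\t600"), header = TRUE)
  net2 <- load_network(tf2, score_threshold = 0.7, score_scale = "string999")
  expect_equal(igraph::ecount(net2), 1)
  expect_equal(igraph::E(net2)$confidence, 0.95)

  # self-loops dropped with a message; duplicates keep the max score
  tf3 <- write_edges_tsv(c("A\tA\t0.99", "A\tB\t0.71", "B\tA\t0.92"))
  expect_message(net3 <- load_network(tf3), "self-loop")
  expect_equal(igraph::ecount(net3), 1)
  expect_equal(igraph::E(net3)$confidence, 0.92)

  # errors: malformed row names the line; bad threshold rejected
  tf4 <- write_edges_tsv(c("A\tB\t0.9", "C\tD"))
  expect_error(load_network(tf4), "line 2")
  tf5 <- write_edges_tsv(c("A\tB\t0.9", "B\tC\tnot_a_number"))
  expect_error(load_network(tf5), "line 2")
  expect_error(load_network(tf, score_threshold = 1.5), "0, 1")
})

test_that("raising the confidence threshold never adds edges", {
  set.seed(42)
  lines <- sprintf("n%d\tn%d\t%.3f", sample(20, 60, TRUE), sample(20, 60, TRUE),
                   runif(60))
  lines <- lines[vapply(strsplit(lines, "\t"), function(r) r[1] != r[2], logical(1))]
  tf <- write_edges_tsv(lines)
  prev <- Inf
  for (thr in c(0, 0.25, 0.5, 0.75, 1)) {
    ec <- igraph::ecount(load_network(tf, score_threshold = thr))
    expect_lte(ec, prev)
    prev <- ec
  }
})

test_that("largest connected component picks size then lexicographic ties", {
  g <- igraph::graph_from_literal(a - b - c - d - e, x - y - z)
  lcc <- largest_connected_component(g)
  expect_setequal(igraph::V(lcc)$name, c("a", "b", "c", "d", "e"))

  # connected network is returned whole
  g2 <- igraph::graph_from_literal(a - b - c)
  expect_equal(igraph::vcount(largest_connected_component(g2)), 3)

  # two size-4 components: lexicographically smallest node list wins
  g3 <- igraph::graph_from_literal(E - F - G - H, A - B - C - D)
  expect_setequal(igraph::V(largest_connected_component(g3))$name,
                  c("A", "B", "C", "D"))

  expect_error(largest_connected_component(igraph::make_empty_graph()), "empty")
})

test_that("degree summary and internal edges match brute-force adjacency math", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  expect_equal(degree_summary(k4, letters[1:4]),
               list(median_degree = 3, min_degree = 3L))

  path <- igraph::graph_from_literal(a - b - c)
  expect_equal(degree_summary(path, c("a", "b")),
               list(median_degree = 1.5, min_degree = 1L))
  expect_error(degree_summary(path, c("a", "zz")), "zz")

  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  expect_equal(internal_edge_count(k5, letters[1:3]), 3)
  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- letters[1:5]
  expect_equal(internal_edge_count(star, letters[2:5]), 0)  # leaves only

  for (seed in 1:6) {
    g <- make_er_graph(12, 0.3, seed)
    adj <- adjacency_of(g)
    genes <- sample(rownames(adj), 6)
    expect_equal(degree_summary(g, genes)$median_degree,
                 median(rowSums(adj)[genes]))
    expect_equal(degree_summary(g, genes)$min_degree,
                 min(rowSums(adj)[genes]))
    expect_equal(internal_edge_count(g, genes),
                 sum(adj[genes, genes]) / 2)
  }
})

test_that("connectivity permutation test flags planted cliques and matches the exhaustive null", {
  set.seed(3)
  g <- igraph::sample_gnp(100, 0.03)
  igraph::V(g)$name <- sprintf("n%03d", 1:100)
  clique_nodes <- sprintf("n%03d", 1:6)
  for (p in combn(clique_nodes, 2, simplify = FALSE)) {
    if (!igraph::are_adjacent(g, p[1], p[2])) g <- igraph::add_edges(g, p)
  }
  res <- connectivity_permutation_test(g, clique_nodes, n_perm = 1000, seed = 9)
  expect_equal(res$observed, 15)
  expect_lte(res$p, 0.01)

  # genes = all nodes: every draw is the whole node set
  small <- make_er_graph(8, 0.4, 5)
  all_res <- connectivity_permutation_test(small, igraph::V(small)$name,
                                           n_perm = 50, seed = 1)
  expect_equal(all_res$p, 1)

  # Monte-Carlo null mean vs exhaustive average over all C(6,3) subsets
  g6 <- make_er_graph(6, 0.5, 11)
  adj <- adjacency_of(g6)
  subsets <- combn(rownames(adj), 3, simplify = FALSE)
  exact_mean <- mean(vapply(subsets, function(s) sum(adj[s, s]) / 2, numeric(1)))
  mc <- connectivity_permutation_test(g6, rownames(adj)[1:3],
                                      n_perm = 4000, seed = 2)
  expect_lt(abs(mc$null_mean - exact_mean), 0.1)

  expect_error(connectivity_permutation_test(g6, rownames(adj)[1:3], n_perm = 0),
               "n_perm")
})

test_that("connectivity permutation p-values are calibrated for random gene sets", {
  # denser graph and larger gene sets keep the internal-edge statistic
  # nearly continuous, so empirical p-values approach uniformity
  g <- make_er_graph(60, 0.2, 77)
  nodes <- igraph::V(g)$name
  ps <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    genes <- sample(nodes, 15)
    connectivity_permutation_test(g, genes, n_perm = 199, seed = i)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("mean shortest-path test recovers tight sets and matches the BFS oracle", {
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  res <- mean_shortest_path_test(k5, letters[1:4], n_random = 10, seed = 1)
  expect_equal(res$observed_mean, 1.0)

  for (seed in 1:5) {
    g <- make_er_graph(10, 0.35, seed + 20)
    lcc <- largest_connected_component(g)
    adj <- adjacency_of(lcc)
    d_oracle <- oracle_shortest_paths(adj)
    d_pkg <- igraph::distances(lcc)
    expect_equal(d_pkg[rownames(d_oracle), colnames(d_oracle)],
                 d_oracle, ignore_attr = TRUE)
  }

  # planted clique inside a ring is closer-knit than random draws
  ring <- igraph::make_ring(30)
  igraph::V(ring)$name <- sprintf("r%02d", 1:30)
  cl <- sprintf("r%02d", c(1, 2, 3, 4))
  for (p in combn(cl, 2, simplify = FALSE)) {
    if (!igraph::are_adjacent(ring, p[1], p[2])) ring <- igraph::add_edges(ring, p)
  }
  res2 <- mean_shortest_path_test(ring, cl, n_random = 200, seed = 4)
  expect_lt(res2$p, 0.01)

  expect_error(mean_shortest_path_test(k5, "a", n_random = 10), "2")
})
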