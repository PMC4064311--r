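test_that("maximal clique enumeration is exact and deterministically ordered", {
  g <- igraph::graph_from_literal(a - b, b - c, a - c, c - d)
  cl <- enumerate_maximal_cliques(g)
  expect_equal(cl$genes, list(c("a", "b", "c"), c("c", "d")))

  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  expect_equal(enumerate_maximal_cliques(k4)$genes, list(letters[1:4]))

  expect_error(enumerate_maximal_cliques(g, min_size = 1), "min_size")

  # deterministic order: size descending, then lexicographic
  g2 <- make_er_graph(10, 0.5, 3)
  cl2 <- enumerate_maximal_cliques(g2)
  sizes <- lengths(cl2$genes)
  expect_true(all(diff(sizes) <= 0))
  keys <- vapply(cl2$genes, paste, character(1), collapse = "|")
  for (s in unique(sizes)) {
    expect_false(is.unsorted(keys[sizes == s]))
  }
})

test_that("clique enumeration matches the exhaustive-subset oracle on random graphs", {
  for (seed in 1:10) {
    g <- make_er_graph(10, 0.5, seed + 100)
    got <- enumerate_maximal_cliques(g)$genes
    want <- oracle_max_cliques(adjacency_of(g))
    key <- function(l) sort(vapply(l, paste, character(1), collapse = "|"))
    expect_equal(key(got), key(want))
  }
})

test_that("clique weights sum -log10 P with p = 1 for unmeasured genes", {
  g <- igraph::graph_from_literal(a - b, c - d)
  cl <- enumerate_maximal_cliques(g)
  de <- de_result(data.frame(gene = c("a", "b", "c"),
                             t = c(1, 1, 1), p = c(0.1, 0.01, 0.001), df = 4))
  w <- weigh_cliques(cl, de)
  named <- setNames(w$weight, vapply(w$genes, paste, character(1), collapse = ""))
  expect_equal(unname(named["ab"]), 3.0)   # 1 + 2
  expect_equal(unname(named["cd"]), 3.0)   # measured 0.001 + unmeasured 0

  de1 <- de_result(data.frame(gene = c("a", "b"), t = c(0, 0), p = c(1, 1), df = 4))
  w1 <- weigh_cliques(cl, de1)
  expect_equal(w1$weight[lengths(w1$genes) == 2][1], 0)

  bad <- data.frame(gene = "a", t = 0, p = 0, df = 4)
  class(bad) <- c("de_result", "data.frame")
  expect_error(weigh_cliques(cl, bad), "positive")
})

test_that("clique significance hits the floor for the best-loaded clique", {
  # clique holding the smallest P-values in the universe: no shuffle can
  # beat it, so its empirical P is exactly 1/(n_perm + 1)
  g <- make_er_graph(30, 0.15, 17)
  nodes <- igraph::V(g)$name
  cl <- enumerate_maximal_cliques(g)
  big <- cl$genes[[1]]
  p <- runif(length(nodes), 0.2, 1)
  names(p) <- nodes
  p[big] <- 1e-8
  de <- de_result(data.frame(gene = nodes, t = 0, p = unname(p), df = 10))
  sig <- clique_significance(cl, de, n_perm = 200, seed = 3)
  expect_equal(sig$empirical_p[1], 1 / 201)
})

test_that("module assembly unions significant cliques and shrinks with alpha", {
  cl <- structure(list(genes = list(c("a", "b", "c"), c("c", "d", "e"), c("x", "y")),
                       weight = c(5, 4, 1),
                       empirical_p = c(0.001, 0.005, 0.5)),
                  class = "clique_set")
  mod <- assemble_module(cl, alpha = 0.01, disease_name = "toy")
  expect_setequal(mod$genes, c("a", "b", "c", "d", "e"))
  expect_equal(length(mod$source_cliques$genes), 2)

  # shrinking alpha never grows the module
  prev <- mod$genes
  for (a in c(0.004, 0.0005)) {
    m <- assemble_module(cl, alpha = a)
    expect_true(all(m$genes %in% prev))
    prev <- m$genes
  }

  none <- assemble_module(structure(list(genes = list(c("a", "b")),
                                         weight = 1, empirical_p = 0.9),
                                    class = "clique_set"), alpha = 0.01)
  expect_equal(none$genes, character(0))
  expect_error(assemble_module(cl, alpha = 1.5), "alpha")
})

test_that("module detection recovers a planted clique and is seed-stable", {
  set.seed(8)
  g <- igraph::sample_pa(300, power = 1, m = 2, directed = FALSE)
  igraph::V(g)$name <- sprintf("g%03d", 1:300)
  planted <- sprintf("g%03d", 1:8)
  for (pr in combn(planted, 2, simplify = FALSE)) {
    if (!igraph::are_adjacent(g, pr[1], pr[2])) g <- igraph::add_edges(g, pr)
  }
  nodes <- igraph::V(g)$name
  set.seed(9)
  pvals <- setNames(runif(length(nodes)), nodes)
  pvals[planted] <- 1e-6
  de <- de_result(data.frame(gene = nodes, t = 0, p = unname(pvals), df = 18))

  mod <- detect_disease_module(g, de, n_perm = 1000, alpha = 0.01, seed = 21,
                               verbose = FALSE)
  expect_true(all(planted %in% mod$genes))

  # doubling n_perm leaves the planted-clique recovery unchanged
  mod2 <- detect_disease_module(g, de, n_perm = 2000, alpha = 0.01, seed = 21,
                                verbose = FALSE)
  expect_true(all(planted %in% mod2$genes))

  # all p = 1: every permutation ties the observed weight, nothing passes
  de1 <- de_result(data.frame(gene = nodes, t = 0, p = 1, df = 18))
  mod_null <- detect_disease_module(g, de1, n_perm = 100, alpha = 0.01,
                                    seed = 1, verbose = FALSE)
  expect_equal(mod_null$genes, character(0))
})

test_that("module membership ignores clique order and survives gene relabeling", {
  g <- make_er_graph(40, 0.2, 55)
  nodes <- igraph::V(g)$name
  planted <- nodes[1:5]
  for (pr in combn(planted, 2, simplify = FALSE)) {
    if (!igraph::are_adjacent(g, pr[1], pr[2])) g <- igraph::add_edges(g, pr)
  }
  set.seed(56)
  pvals <- setNames(runif(length(nodes), 0.3, 1), nodes)
  pvals[planted] <- 1e-6
  de <- de_result(data.frame(gene = nodes, t = 0, p = unname(pvals), df = 10))

  cl <- enumerate_maximal_cliques(g)
  cl <- weigh_cliques(cl, de)
  sig <- clique_significance(cl, de, n_perm = 300, seed = 12)
  mod <- assemble_module(sig, alpha = 0.01)

  # shuffling clique order changes nothing: per-clique nulls share the
  # same global shuffles regardless of position
  perm <- rev(seq_along(cl$genes))
  cl_r <- structure(list(genes = cl$genes[perm], weight = cl$weight[perm],
                         empirical_p = rep(NA_real_, length(perm))),
                    class = "clique_set")
  sig_r <- clique_significance(cl_r, de, n_perm = 300, seed = 12)
  mod_r <- assemble_module(sig_r, alpha = 0.01)
  expect_setequal(mod$genes, mod_r$genes)

  # a bijective rename of network + DE table recovers the renamed
  # planted module (signal is unambiguous, so the stochastic null
  # cannot flip it)
  rename <- setNames(sprintf("R%02d", seq_along(nodes)), nodes)
  g2 <- g
  igraph::V(g2)$name <- unname(rename[igraph::V(g)$name])
  de2 <- de_result(data.frame(gene = unname(rename[de$gene]), t = de$t,
                              p = de$p, df = de$df))
  mod2 <- detect_disease_module(g2, de2, n_perm = 300, seed = 12,
                                verbose = FALSE)
  expect_true(all(rename[planted] %in% mod2$genes))
  expect_true(all(planted %in% mod$genes))
})
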