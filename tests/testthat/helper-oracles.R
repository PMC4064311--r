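# Independent brute-force oracles used to validate the package's
# implementations on small instances, plus small fixture builders.

# All maximal cliques (size >= min_size) of an adjacency matrix by
# exhaustive enumeration of every vertex subset. n must be small.
oracle_max_cliques <- function(adj, min_size = 2L) {
  n <- nrow(adj)
  stopifnot(n <= 15)
  nodes <- rownames(adj)
  out <- list()
  for (mask in seq_len(2^n - 1L)) {
    members <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    if (length(members) < min_size) next
    sub <- adj[members, members, drop = FALSE]
    if (any(sub[upper.tri(sub)] == 0)) next       # not a clique
    outside <- setdiff(seq_len(n), members)
    extendable <- any(vapply(outside, function(v) {
      all(adj[v, members] == 1)
    }, logical(1L)))
    if (!extendable) out[[length(out) + 1L]] <- sort(nodes[members])
  }
  out
}

# Literal Benjamini-Hochberg step-up: sort, q_i = min_{j >= i} p_j * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# All-pairs shortest paths by repeated boolean matrix products.
oracle_shortest_paths <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  diag(d) <- 0
  pow <- diag(n)
  for (k in seq_len(n)) {
    pow <- pow %*% adj
    hit <- pow > 0 & !is.finite(d)
    d[hit] <- k
  }
  d
}

# Hypergeometric upper tail P(X >= k) by exhaustive draw enumeration.
oracle_hyper_upper <- function(k, n, K, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  annotated <- seq_len(K)
  hits <- apply(draws, 2L, function(s) sum(s %in% annotated))
  mean(hits >= k)
}

# Seeded Erdos-Renyi graph with named vertices.
make_er_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

adjacency_of <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g))
}

# Gaussian two-group expression study.
make_study <- function(n_genes, n_case, n_control, shift_genes = character(),
                       shift = 0, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  m <- matrix(rnorm(n_genes * (n_case + n_control)), nrow = n_genes,
              dimnames = list(genes, sprintf("s%02d", seq_len(n_case + n_control))))
  m[shift_genes, seq_len(n_case)] <- m[shift_genes, seq_len(n_case)] + shift
  expression_study(m, c(rep("case", n_case), rep("control", n_control)))
}

# Enrichment p against unconstrained uniform random gene sets (the
# biased null that degree matching is meant to replace).
uniform_null_enrichment_p <- function(net, test_set, annotation, n_sets, seed) {
  set.seed(seed)
  nodes <- igraph::V(net)$name
  obs <- length(intersect(test_set, annotation))
  null_k <- vapply(seq_len(n_sets), function(b) {
    length(intersect(sample(nodes, length(test_set)), annotation))
  }, integer(1))
  (sum(null_k >= obs) + 1) / (n_sets + 1)
}

write_edges_tsv <- function(lines, header = FALSE) {
  tf <- tempfile(fileext = ".tsv")
  if (header) lines <- c("gene_a\tgene_b\tscore", lines)
  writeLines(lines, tf)
  tf
}
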