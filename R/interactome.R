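#' Load a gene-gene interaction network from an edge-list file
#'
#' Reads a tab-separated edge list (columns: gene A, gene B, confidence
#' score, optional header) into an undirected [igraph][igraph::igraph]
#' graph with a `confidence` edge attribute in \[0, 1\]. Edges below the
#' confidence threshold are discarded, self-loops are dropped, and
#' duplicate gene pairs keep the maximum score.
#'
#' @param path Path to the TSV edge list.
#' @param score_threshold Minimum normalized confidence for an edge to be
#'   kept; must lie in \[0, 1\]. Default 0.7, the conventional
#'   high-confidence cutoff for STRING-style networks.
#' @param score_scale Either `"unit"` (scores already in \[0, 1\]) or
#'   `"string999"` (STRING-style integer scores in 0-999, divided by 1000).
#' @return An undirected `igraph` object whose vertex names are gene
#'   identifiers and whose edges carry a `confidence` attribute.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("A\tB\t0.9", "B\tC\t0.6", "A\tC\t0.8"), tf)
#' net <- load_network(tf, score_threshold = 0.7)
#' igraph::ecount(net)  # 2: the 0.6 edge is filtered out
#' @export
load_network <- function(path, score_threshold = 0.7,
                         score_scale = c("unit", "string999")) {
  score_scale <- match.arg(score_scale)
  if (!is.numeric(score_threshold) || length(score_threshold) != 1L ||
      is.na(score_threshold) || score_threshold < 0 || score_threshold > 1) {
    stop("`score_threshold` must be a single number in [0, 1]", call. = FALSE)
  }
  if (!file.exists(path)) stop("network file not found: ", path, call. = FALSE)

  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty network file: ", path, call. = FALSE)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- fields[[1L]]
  has_header <- length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[3L])))
  start <- if (has_header) 2L else 1L
  if (start > length(fields)) stop("network file has a header but no rows", call. = FALSE)

  n_rows <- length(fields) - start + 1L
  ga <- gb <- character(n_rows)
  sc <- numeric(n_rows)
  for (i in seq_len(n_rows)) {
    row <- fields[[start + i - 1L]]
    if (length(row) < 3L) {
      stop("malformed edge row at line ", start + i - 1L,
           ": expected at least 3 tab-separated fields", call. = FALSE)
    }
    s <- suppressWarnings(as.numeric(row[3L]))
    if (is.na(s)) {
      stop("malformed edge row at line ", start + i - 1L,
           ": non-numeric score '", row[3L], "'", call. = FALSE)
    }
    ga[i] <- row[1L]; gb[i] <- row[2L]; sc[i] <- s
  }

  if (score_scale == "string999") sc <- sc / 1000
  if (any(sc < 0 | sc > 1)) {
    stop("normalized confidence scores outside [0, 1]; check `score_scale`",
         call. = FALSE)
  }

  loops <- ga == gb
  if (any(loops)) {
    message("dropping ", sum(loops), " self-loop(s)")
    ga <- ga[!loops]; gb <- gb[!loops]; sc <- sc[!loops]
  }

  # canonical unordered pair; duplicates keep the maximum score
  a <- pmin(ga, gb)
  b <- pmax(ga, gb)
  key <- paste(a, b, sep = "\r")
  best <- tapply(sc, key, max)
  keys <- names(best)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  edges <- data.frame(
    from = vapply(parts, `[`, character(1L), 1L),
    to = vapply(parts, `[`, character(1L), 2L),
    confidence = as.numeric(best),
    stringsAsFactors = FALSE
  )
  edges <- edges[edges$confidence >= score_threshold, , drop = FALSE]
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

#' Extract the largest connected component
#'
#' Returns the induced subgraph on the largest connected component. Size
#' ties are broken deterministically in favour of the component whose
#' sorted vertex-name list is lexicographically smallest.
#'
#' @param net An undirected `igraph` network.
#' @return An `igraph` subgraph.
#' @export
largest_connected_component <- function(net) {
  if (igraph::vcount(net) == 0L) stop("network is empty", call. = FALSE)
  comp <- igraph::components(net)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    keys <- vapply(best, function(ci) {
      paste(sort(names(comp$membership)[comp$membership == ci]), collapse = "\r")
    }, character(1L))
    best <- best[order(keys)][1L]
  }
  keep <- names(comp$membership)[comp$membership == best]
  igraph::induced_subgraph(net, keep)
}

check_genes_in_network <- function(net, genes) {
  genes <- unique(as.character(genes))
  missing <- setdiff(genes, igraph::V(net)$name)
  if (length(missing) > 0L) {
    stop("gene(s) absent from network: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) ", ..." else "", call. = FALSE)
  }
  genes
}

#' Degree summary of a gene set within the full network
#'
#' Computes the median and minimum degree of a gene set, with degrees
#' taken in the full network (not the induced subgraph). Even-sized sets
#' use the midpoint median.
#'
#' @param net An `igraph` network.
#' @param genes Character vector of gene identifiers, all present in `net`.
#' @return A list with elements `median_degree` and `min_degree`.
#' @export
degree_summary <- function(net, genes) {
  genes <- check_genes_in_network(net, genes)
  d <- igraph::degree(net, v = genes)
  list(median_degree = as.numeric(stats::median(d)),
       min_degree = as.integer(min(d)))
}

#' Count network edges internal to a gene set
#'
#' @inheritParams degree_summary
#' @return Integer number of edges with both endpoints in `genes`.
#' @export
internal_edge_count <- function(net, genes) {
  genes <- check_genes_in_network(net, genes)
  igraph::ecount(igraph::induced_subgraph(net, genes))
}

#' Permutation test of internal connectivity
#'
#' Tests whether a gene set has more internal edges than same-size gene
#' sets drawn uniformly from the network. The empirical P-value uses the
#' (r + 1) / (n + 1) estimator, where r counts null draws with at least as
#' many internal edges as observed.
#'
#' @inheritParams degree_summary
#' @param n_perm Number of random gene sets to draw (>= 1).
#' @param seed Integer seed for reproducibility.
#' @return A list with `observed`, `null_mean`, and `p`.
#' @export
connectivity_permutation_test <- function(net, genes, n_perm = 1000L, seed = 1L) {
  genes <- check_genes_in_network(net, genes)
  if (!is.numeric(n_perm) || n_perm < 1) {
    stop("`n_perm` must be >= 1", call. = FALSE)
  }
  n_perm <- as.integer(n_perm)
  adj <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  nodes <- igraph::V(net)$name
  idx_obs <- match(genes, nodes)
  observed <- as.integer(sum(adj[idx_obs, idx_obs]) / 2)

  k <- length(genes)
  null_counts <- integer(n_perm)
  withr_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(length(nodes), k)
      null_counts[b] <- sum(adj[idx, idx]) / 2
    }
  })
  r <- sum(null_counts >= observed)
  list(observed = observed,
       null_mean = mean(null_counts),
       p = (r + 1) / (n_perm + 1))
}

#' Mean shortest-path test for a gene set
#'
#' Compares the mean unweighted shortest-path length among a gene set
#' against same-size random sets drawn from the largest connected
#' component, using a one-sided Wilcoxon signed-rank test of the null
#' means against the observed mean (alternative: null means are larger,
#' i.e. the observed set is closer-knit than random).
#'
#' @inheritParams degree_summary
#' @param n_random Number of random gene sets (>= 2).
#' @param seed Integer seed.
#' @return A list with `observed_mean`, `null_means`, and `p`.
#' @export
mean_shortest_path_test <- function(net, genes, n_random = 1000L, seed = 1L) {
  if (!is.numeric(n_random) || n_random < 2) {
    stop("`n_random` must be >= 2", call. = FALSE)
  }
  n_random <- as.integer(n_random)
  lcc <- largest_connected_component(net)
  genes <- intersect(unique(as.character(genes)), igraph::V(lcc)$name)
  if (length(genes) < 2L) {
    stop("fewer than 2 query genes fall in the largest connected component",
         call. = FALSE)
  }
  mean_pair_dist <- function(g, vs) {
    d <- igraph::distances(g, v = vs, to = vs)
    mean(d[upper.tri(d)])
  }
  observed_mean <- mean_pair_dist(lcc, genes)
  nodes <- igraph::V(lcc)$name
  k <- length(genes)
  null_means <- numeric(n_random)
  withr_seed(seed, {
    for (b in seq_len(n_random)) {
      null_means[b] <- mean_pair_dist(lcc, sample(nodes, k))
    }
  })
  p <- stats::wilcox.test(null_means, mu = observed_mean,
                          alternative = "greater", exact = FALSE)$p.value
  list(observed_mean = observed_mean, null_means = null_means, p = p)
}

#' Degree constraint for matched random gene sets
#'
#' Bundles the target profile used when sampling random gene sets matched
#' to a test set's connectivity: set size, target median degree, minimum
#' degree, and the absolute tolerance allowed on the achieved median.
#'
#' @param set_size Number of genes per sampled set.
#' @param median_degree Target median degree (positive).
#' @param min_degree Minimum degree every sampled gene must have.
#' @param tolerance Absolute tolerance on the achieved median degree;
#'   defaults to 2% of `median_degree`.
#' @return An object of class `degree_constraint`.
#' @export
degree_constraint <- function(set_size, median_degree, min_degree,
                              tolerance = 0.02 * median_degree) {
  stopifnot(set_size >= 1, median_degree > 0, min_degree >= 1, tolerance >= 0)
  if (min_degree > median_degree) {
    stop("`min_degree` must not exceed `median_degree`", call. = FALSE)
  }
  structure(list(set_size = as.integer(set_size),
                 median_degree = as.numeric(median_degree),
                 min_degree = as.integer(min_degree),
                 tolerance = as.numeric(tolerance)),
            class = "degree_constraint")
}

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards so library randomness never leaks.
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed) %% .Machine$integer.max)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(expr))
}
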