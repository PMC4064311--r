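#' Fold enrichment of a feature in a test set
#'
#' Fold enrichment (FE) is the frequency of a feature among the tested
#' genes divided by its frequency in the universe: `(k/n) / (K/N)`. For
#' example, 53 annotated genes in a 158-gene set against 2,298 of 22,500
#' in the universe gives 33.5% / 10.2% = 3.3.
#'
#' @param k Annotated genes in the test set.
#' @param n Test set size (> 0).
#' @param K Annotated genes in the universe (> 0).
#' @param N Universe size.
#' @return The fold enrichment, a non-negative real.
#' @export
fold_enrichment <- function(k, n, K, N) {
  check_counts(k, n, K, N)
  if (n == 0) stop("test set size `n` must be positive", call. = FALSE)
  if (K == 0) stop("`K` must be positive: feature absent from universe", call. = FALSE)
  (k / n) / (K / N)
}

check_counts <- function(k, n, K, N) {
  vals <- c(k = k, n = n, K = K, N = N)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals != round(vals))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (k > min(n, K) || n > N || K > N) {
    stop("inconsistent counts: need k <= min(n, K), n <= N, K <= N",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' One-sided Fisher / hypergeometric enrichment P-value
#'
#' Upper-tail probability `P(X >= k)` for a hypergeometric draw of `n`
#' genes from a universe of `N` containing `K` annotated genes; the
#' one-sided Fisher exact test of over-representation.
#'
#' @inheritParams fold_enrichment
#' @return A P-value in (0, 1].
#' @export
fisher_enrichment <- function(k, n, K, N) {
  check_counts(k, n, K, N)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted P-values
#'
#' Step-up false-discovery-rate adjustment; input order is preserved and
#' adjusted values are capped at 1.
#'
#' @param p_values Numeric vector of P-values in (0, 1].
#' @return Adjusted P-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("P-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Sample degree-matched random gene sets
#'
#' Draws random gene sets matched to a target connectivity profile: every
#' sampled gene has degree at least `constraint$min_degree`, and the
#' achieved median degree lies within `constraint$tolerance` of
#' `constraint$median_degree`. Sampling stratifies each draw into halves
#' above and below the target median (within the eligible pool) and then
#' rejects draws whose median misses the tolerance band.
#'
#' @param net An `igraph` network.
#' @param constraint A [degree_constraint()].
#' @param n_sets Number of sets to return.
#' @param seed Integer seed.
#' @param max_tries Bound on rejection attempts per accepted set (on
#'   average); exceeded means the constraint is infeasible as posed.
#' @return A list of `n_sets` character vectors.
#' @export
degree_matched_sets <- function(net, constraint, n_sets = 1000L, seed = 1L,
                                max_tries = 200L) {
  stopifnot(inherits(constraint, "degree_constraint"))
  deg <- igraph::degree(net)
  pool <- names(deg)[deg >= constraint$min_degree]
  if (length(pool) < constraint$set_size) {
    stop("infeasible constraint: only ", length(pool), " gene(s) have degree >= ",
         constraint$min_degree, " but set_size = ", constraint$set_size,
         call. = FALSE)
  }
  pd <- deg[pool]
  hi <- pool[pd >= constraint$median_degree]
  lo <- pool[pd < constraint$median_degree]
  n_hi <- ceiling(constraint$set_size / 2)
  n_lo <- constraint$set_size - n_hi
  if (length(hi) < n_hi || length(lo) < n_lo) {
    stop("infeasible constraint: pool has ", length(hi), " gene(s) at/above and ",
         length(lo), " below the target median degree (need ", n_hi, " and ",
         n_lo, ")", call. = FALSE)
  }
  sets <- vector("list", n_sets)
  withr_seed(seed, {
    accepted <- 0L
    tries <- 0L
    budget <- as.numeric(max_tries) * n_sets
    while (accepted < n_sets) {
      tries <- tries + 1L
      if (tries > budget) {
        stop("degree-matched sampling exceeded ", format(budget),
             " attempts with ", accepted, "/", n_sets, " sets accepted; ",
             "median tolerance ", constraint$tolerance,
             " around target ", constraint$median_degree,
             " appears infeasible for this network", call. = FALSE)
      }
      s <- c(sample(hi, n_hi), sample(lo, n_lo))
      if (abs(stats::median(deg[s]) - constraint$median_degree) <=
          constraint$tolerance) {
        accepted <- accepted + 1L
        sets[[accepted]] <- s
      }
    }
  })
  sets
}

#' Degree-controlled annotation enrichment
#'
#' Tests whether a gene set holds more annotated genes than random sets
#' matched to its degree profile, removing hub bias from the enrichment
#' P-value. P is (r + 1) / (n_sets + 1), with r the number of matched null
#' sets with at least as many annotated members as observed.
#'
#' @param net An `igraph` network.
#' @param test_set Character vector of genes.
#' @param annotation Character vector of annotated genes.
#' @param constraint A [degree_constraint()]; defaults to the profile of
#'   `test_set` itself.
#' @param n_sets Number of matched null sets.
#' @param seed Integer seed.
#' @return A list with `observed_k`, `null_k`, and `p`.
#' @export
degree_controlled_enrichment <- function(net, test_set, annotation,
                                         constraint = NULL, n_sets = 1000L,
                                         seed = 1L) {
  test_set <- check_genes_in_network(net, test_set)
  if (is.null(constraint)) {
    ds <- degree_summary(net, test_set)
    constraint <- degree_constraint(length(test_set), ds$median_degree,
                                    ds$min_degree)
  }
  sets <- degree_matched_sets(net, constraint, n_sets = n_sets, seed = seed)
  observed_k <- length(intersect(test_set, annotation))
  null_k <- vapply(sets, function(s) length(intersect(s, annotation)),
                   integer(1L))
  r <- sum(null_k >= observed_k)
  list(observed_k = observed_k, null_k = null_k, p = (r + 1) / (n_sets + 1))
}

#' Correlation screen of a gene set against response profiles
#'
#' For each response vector (one per agent, e.g. drug sensitivity across
#' cell lines), scores the gene set by the mean absolute Pearson
#' correlation between each member gene's expression and the response,
#' and compares it with same-size random gene sets drawn from the
#' measured universe. The same random sets are reused across agents; BH
#' FDR is applied across agents. Agents with a constant response vector
#' are skipped with a warning.
#'
#' @param expr Numeric genes-by-samples expression matrix with row names.
#' @param responses Numeric samples-by-agents matrix (column names are
#'   agent identifiers), rows aligned with `expr` columns.
#' @param genes Gene set to score; must be measured in `expr`.
#' @param n_random Number of random gene sets (>= 2).
#' @param fdr FDR threshold for flagging agents.
#' @param seed Integer seed.
#' @return A data frame with columns `agent`, `score`, `p`, `q`, `flagged`.
#' @export
geneset_correlation_screen <- function(expr, responses, genes,
                                       n_random = 1000L, fdr = 0.05,
                                       seed = 1L) {
  expr <- as.matrix(expr)
  responses <- as.matrix(responses)
  if (nrow(responses) != ncol(expr)) {
    stop("`responses` rows must align with `expr` samples", call. = FALSE)
  }
  if (!is.numeric(n_random) || n_random < 2) {
    stop("`n_random` must be >= 2", call. = FALSE)
  }
  n_random <- as.integer(n_random)
  genes <- unique(as.character(genes))
  if (!all(genes %in% rownames(expr))) {
    stop("gene(s) missing from expression matrix", call. = FALSE)
  }
  if (is.null(colnames(responses))) {
    colnames(responses) <- paste0("agent", seq_len(ncol(responses)))
  }
  constant <- apply(responses, 2L, stats::sd) == 0
  if (any(constant)) {
    warning("skipping constant response vector(s): ",
            paste(colnames(responses)[constant], collapse = ", "))
  }
  agents <- colnames(responses)[!constant]
  resp <- responses[, !constant, drop = FALSE]

  cg <- stats::cor(t(expr), resp)          # genes x agents
  obs <- colMeans(abs(cg[genes, , drop = FALSE]))

  all_genes <- rownames(expr)
  null_scores <- matrix(NA_real_, n_random, length(agents))
  withr_seed(seed, {
    for (b in seq_len(n_random)) {
      s <- sample(all_genes, length(genes))
      null_scores[b, ] <- colMeans(abs(cg[s, , drop = FALSE]))
    }
  })
  p <- vapply(seq_along(agents), function(j) {
    (sum(null_scores[, j] >= obs[j]) + 1) / (n_random + 1)
  }, numeric(1L))
  q <- bh_fdr(p)
  data.frame(agent = agents, score = unname(obs), p = p, q = q,
             flagged = q < fdr, row.names = NULL, stringsAsFactors = FALSE)
}
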