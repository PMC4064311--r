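#' Enumerate maximal cliques of an interaction network
#'
#' Lists all maximal cliques of size at least `min_size`, using igraph's
#' Bron-Kerbosch enumeration, in a deterministic order: decreasing size,
#' then lexicographic on the sorted member genes. A maximal edge whose
#' endpoints share no common neighbour is itself a maximal clique, so the
#' default floor of 2 keeps every maximal clique.
#'
#' @param net An `igraph` network.
#' @param min_size Minimum clique size (>= 2).
#' @return A `clique_set`: list with `genes` (list of character vectors),
#'   `weight` (numeric, `NA` until [weigh_cliques()]), and `empirical_p`
#'   (numeric, `NA` until [clique_significance()]).
#' @export
enumerate_maximal_cliques <- function(net, min_size = 2L) {
  if (!is.numeric(min_size) || min_size < 2) {
    stop("`min_size` must be >= 2", call. = FALSE)
  }
  cliques <- igraph::max_cliques(net, min = as.integer(min_size))
  genes <- lapply(cliques, function(cl) sort(igraph::V(net)$name[cl]))
  if (length(genes) > 0L) {
    key <- vapply(genes, paste, character(1L), collapse = "\r")
    ord <- order(-lengths(genes), key)
    genes <- genes[ord]
  }
  structure(list(genes = genes,
                 weight = rep(NA_real_, length(genes)),
                 empirical_p = rep(NA_real_, length(genes))),
            class = "clique_set")
}

#' @export
print.clique_set <- function(x, ...) {
  cat("clique_set with", length(x$genes), "maximal clique(s)")
  if (length(x$genes) > 0L) {
    cat("; sizes", min(lengths(x$genes)), "-", max(lengths(x$genes)))
  }
  if (!all(is.na(x$weight))) cat("; weighted")
  if (!all(is.na(x$empirical_p))) cat("; significance computed")
  cat("\n")
  invisible(x)
}

#' @export
length.clique_set <- function(x) length(x$genes)

#' Weigh cliques by differential expression
#'
#' Assigns each clique the weight `sum(-log10(p))` over its member genes'
#' differential-expression P-values. Genes present in the network but
#' absent from the DE table contribute 0 (treated as p = 1), so cliques
#' spanning unmeasured genes are kept rather than discarded.
#'
#' @param cliques A `clique_set` from [enumerate_maximal_cliques()].
#' @param de A `de_result` with columns `gene` and `p`.
#' @return The `clique_set` with `weight` filled in.
#' @export
weigh_cliques <- function(cliques, de) {
  stopifnot(inherits(cliques, "clique_set"), inherits(de, "de_result"))
  if (any(de$p <= 0)) stop("P-values must be strictly positive", call. = FALSE)
  nlp <- -log10(de$p)
  names(nlp) <- de$gene
  cliques$weight <- vapply(cliques$genes, function(g) {
    w <- nlp[g]
    sum(w[!is.na(w)])
  }, numeric(1L))
  cliques
}

# Sparse clique-by-gene incidence matrix over `universe`.
clique_incidence <- function(cliques, universe) {
  j <- match(unlist(cliques$genes), universe)
  i <- rep.int(seq_along(cliques$genes), lengths(cliques$genes))
  keep <- !is.na(j)
  Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                       dims = c(length(cliques$genes), length(universe)))
}

#' Empirical clique significance by gene-P randomization
#'
#' For each permutation, the gene-to-P-value assignment is shuffled once
#' globally over the gene universe and all clique weights are recomputed
#' on that shared shuffle, which preserves the inter-clique correlation of
#' the null. Each clique's empirical P is (r + 1) / (n_perm + 1) with r
#' the number of permutations whose weight is at least the real weight.
#'
#' @param cliques A weighted `clique_set` (see [weigh_cliques()]).
#' @param de A `de_result`.
#' @param n_perm Number of gene-P randomizations (>= 1; 10,000 is the
#'   conventional default at full scale).
#' @param seed Integer seed.
#' @param universe Which gene universe the P-values are shuffled over:
#'   `"union"` (network clique genes plus measured genes, the default),
#'   `"network"`, or `"measured"`. Genes in the universe without a
#'   measured P contribute weight 0, and shuffling moves those zeros
#'   around like any other value.
#' @param block_size Number of permutations evaluated per matrix product;
#'   memory/speed trade-off only.
#' @return The `clique_set` with `empirical_p` filled in.
#' @export
clique_significance <- function(cliques, de, n_perm = 10000L, seed = 1L,
                                universe = c("union", "network", "measured"),
                                block_size = 500L) {
  stopifnot(inherits(cliques, "clique_set"), inherits(de, "de_result"))
  universe <- match.arg(universe)
  if (!is.numeric(n_perm) || n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  n_perm <- as.integer(n_perm)
  if (any(is.na(cliques$weight))) cliques <- weigh_cliques(cliques, de)
  if (length(cliques$genes) == 0L) return(cliques)

  net_genes <- unique(unlist(cliques$genes))
  # canonical (sorted) universe: the null is then independent of clique
  # order and of the row order of the DE table
  uni <- sort(switch(universe,
                     union = union(net_genes, de$gene),
                     network = net_genes,
                     measured = de$gene))
  w <- rep(0, length(uni))
  idx <- match(de$gene, uni)
  w[idx[!is.na(idx)]] <- -log10(de$p[!is.na(idx)])

  M <- clique_incidence(cliques, uni)
  observed <- as.numeric(M %*% w)
  r <- integer(length(observed))
  withr_seed(seed, {
    done <- 0L
    while (done < n_perm) {
      nb <- min(block_size, n_perm - done)
      P <- vapply(seq_len(nb), function(b) sample(w), numeric(length(w)))
      W <- as.matrix(M %*% P)
      r <- r + rowSums(W >= observed - 1e-12)
      done <- done + nb
    }
  })
  cliques$empirical_p <- (r + 1) / (n_perm + 1)
  cliques
}

#' Assemble a disease module from significant cliques
#'
#' The disease module is the union of the genes of all cliques whose
#' empirical P falls below `alpha` (fixed per-clique threshold; no
#' multiplicity correction across cliques). An empty union is allowed.
#'
#' @param cliques A `clique_set` with `empirical_p` populated.
#' @param alpha Per-clique significance threshold in (0, 1); default 0.01.
#' @param disease_name Label stored with the module.
#' @return A `disease_module`: list with `disease_name`, `genes`, and
#'   `source_cliques` (the significant cliques only).
#' @export
assemble_module <- function(cliques, alpha = 0.01, disease_name = "disease") {
  stopifnot(inherits(cliques, "clique_set"))
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (length(cliques$genes) > 0L && any(is.na(cliques$empirical_p))) {
    stop("run clique_significance() before assembling a module", call. = FALSE)
  }
  keep <- which(cliques$empirical_p < alpha)
  sig <- list(genes = cliques$genes[keep],
              weight = cliques$weight[keep],
              empirical_p = cliques$empirical_p[keep])
  class(sig) <- "clique_set"
  structure(list(disease_name = disease_name,
                 genes = sort(unique(as.character(unlist(sig$genes)))),
                 source_cliques = sig),
            class = "disease_module")
}

#' @export
print.disease_module <- function(x, ...) {
  cat("disease_module '", x$disease_name, "': ", length(x$genes),
      " gene(s) from ", length(x$source_cliques$genes),
      " significant clique(s)\n", sep = "")
  invisible(x)
}

#' Detect a disease module from a network and DE P-values
#'
#' End-to-end module detection: enumerate maximal cliques, weigh them by
#' the summed -log10 P of their members, assess each weight against a
#' global gene-P randomization null, and take the union of cliques
#' significant at `alpha`.
#'
#' @inheritParams clique_significance
#' @param net An `igraph` network.
#' @param alpha Per-clique significance threshold; default 0.01.
#' @param min_size Minimum clique size; default 2.
#' @param disease_name Label for the resulting module.
#' @param verbose Log clique counts at each stage.
#' @return A `disease_module`.
#' @export
detect_disease_module <- function(net, de, n_perm = 10000L, alpha = 0.01,
                                  seed = 1L, min_size = 2L,
                                  disease_name = "disease",
                                  universe = "union", verbose = TRUE) {
  cliques <- enumerate_maximal_cliques(net, min_size = min_size)
  if (verbose) message(disease_name, ": ", length(cliques$genes),
                       " maximal clique(s) of size >= ", min_size)
  cliques <- weigh_cliques(cliques, de)
  cliques <- clique_significance(cliques, de, n_perm = n_perm, seed = seed,
                                 universe = universe)
  mod <- assemble_module(cliques, alpha = alpha, disease_name = disease_name)
  if (verbose) message(disease_name, ": ",
                       length(mod$source_cliques$genes),
                       " significant clique(s) -> module of ",
                       length(mod$genes), " gene(s)")
  mod
}
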