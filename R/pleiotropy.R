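#' Intersect disease modules and count per-gene membership
#'
#' @param modules List of at least two `disease_module` objects.
#' @return A list with `intersection` (genes present in every module) and
#'   `module_count` (named integer vector over all genes in any module).
#' @export
intersect_modules <- function(modules) {
  if (length(modules) < 2L) stop("need at least 2 modules", call. = FALSE)
  stopifnot(all(vapply(modules, inherits, logical(1L), "disease_module")))
  gene_lists <- lapply(modules, `[[`, "genes")
  all_genes <- sort(unique(unlist(gene_lists)))
  counts <- integer(length(all_genes))
  names(counts) <- all_genes
  for (g in gene_lists) counts[g] <- counts[g] + 1L
  list(intersection = names(counts)[counts == length(modules)],
       module_count = counts)
}

# Detect one module per disease, reusing a shared clique enumeration.
detect_all_diseases <- function(cliques, de_list, n_perm, alpha, seeds,
                                universe, verbose = FALSE) {
  mods <- vector("list", length(de_list))
  for (d in seq_along(de_list)) {
    cl <- clique_significance(cliques, de_list[[d]], n_perm = n_perm,
                              seed = seeds[d], universe = universe)
    mods[[d]] <- assemble_module(cl, alpha = alpha,
                                 disease_name = names(de_list)[d] %||%
                                   paste0("disease", d))
  }
  mods
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pleiotropic overlap of disease modules against a randomized null
#'
#' Runs module detection for every disease, intersects the resulting
#' modules, and compares the intersection against a null in which each
#' disease's gene-to-P-value assignment is independently shuffled and the
#' entire detection pipeline is rerun. The clique enumeration is shared
#' across all runs since the network never changes.
#'
#' Reported quantities: the empirical P of the observed intersection size,
#' (r + 1) / (n_repeats + 1) with r the number of null repeats reaching at
#' least the observed size; the intersection fold enrichment, observed
#' size over the mean null size (`NA` when the null mean is 0); and a
#' per-gene pleiotropy P, the floored fraction of null repeats in which
#' the gene appears in at least as many disease modules as observed.
#'
#' @param net An `igraph` network.
#' @param de_list Named list of `de_result` tables, one per disease, all
#'   over the same gene universe.
#' @param n_repeats Number of full null repeats (100 at study scale).
#' @param n_perm Clique permutations inside each detection run; the
#'   default 1000 keeps the nested null tractable and is recorded in the
#'   result.
#' @param alpha Per-clique significance threshold.
#' @param min_size Minimum clique size.
#' @param universe Gene universe for P shuffling (see
#'   [clique_significance()]).
#' @param seed Integer seed governing all randomization.
#' @param verbose Log progress.
#' @return A `pleiotropy_result`: list with `diseases`, `modules`,
#'   `intersection`, `module_count`, `null_intersection_sizes`,
#'   `fold_enrichment`, `p`, `per_gene_p`, and `params`.
#' @export
pleiotropy_null <- function(net, de_list, n_repeats = 100L, n_perm = 1000L,
                            alpha = 0.01, min_size = 2L,
                            universe = "union", seed = 1L, verbose = TRUE) {
  if (!is.numeric(n_repeats) || n_repeats < 1) {
    stop("`n_repeats` must be >= 1", call. = FALSE)
  }
  n_repeats <- as.integer(n_repeats)
  stopifnot(length(de_list) >= 2L,
            all(vapply(de_list, inherits, logical(1L), "de_result")))
  universes <- lapply(de_list, function(d) sort(d$gene))
  if (length(unique(vapply(universes, paste, character(1L), collapse = "\r"))) != 1L) {
    stop("all diseases must share the same measured gene universe", call. = FALSE)
  }
  if (is.null(names(de_list))) {
    names(de_list) <- paste0("disease", seq_along(de_list))
  }
  D <- length(de_list)

  cliques <- enumerate_maximal_cliques(net, min_size = min_size)
  if (verbose) message(length(cliques$genes), " maximal clique(s) enumerated")

  n_seeds <- D + n_repeats * (2L * D)
  seeds <- withr_seed(seed, sample.int(.Machine$integer.max - 1L, n_seeds))

  modules <- detect_all_diseases(cliques, de_list, n_perm, alpha,
                                 seeds[seq_len(D)], universe)
  obs <- intersect_modules(modules)
  observed_size <- length(obs$intersection)
  if (verbose) message("observed intersection: ", observed_size, " gene(s)")

  all_net_genes <- igraph::V(net)$name
  obs_count_full <- integer(length(all_net_genes))
  names(obs_count_full) <- all_net_genes
  common <- intersect(names(obs$module_count), all_net_genes)
  obs_count_full[common] <- obs$module_count[common]

  null_sizes <- integer(n_repeats)
  gene_exceed <- integer(length(all_net_genes))
  names(gene_exceed) <- all_net_genes
  si <- D
  for (rep_i in seq_len(n_repeats)) {
    de_shuf <- vector("list", D)
    for (d in seq_len(D)) {
      si <- si + 1L
      de_d <- de_list[[d]]
      perm <- withr_seed(seeds[si], sample.int(nrow(de_d)))
      de_d$p <- de_d$p[perm]
      de_d$t <- de_d$t[perm]
      de_shuf[[d]] <- de_d
    }
    names(de_shuf) <- names(de_list)
    det_seeds <- seeds[si + seq_len(D)]
    si <- si + D
    null_mods <- detect_all_diseases(cliques, de_shuf, n_perm, alpha,
                                     det_seeds, universe)
    null_counts <- integer(length(all_net_genes))
    names(null_counts) <- all_net_genes
    for (m in null_mods) null_counts[m$genes] <- null_counts[m$genes] + 1L
    null_sizes[rep_i] <- sum(null_counts == D)
    gene_exceed <- gene_exceed + (null_counts >= obs_count_full)
    if (verbose && rep_i %% 10L == 0L) {
      message("null repeat ", rep_i, "/", n_repeats,
              " (intersection size ", null_sizes[rep_i], ")")
    }
  }

  r <- sum(null_sizes >= observed_size)
  fe <- if (mean(null_sizes) == 0) NA_real_ else observed_size / mean(null_sizes)
  structure(list(
    diseases = names(de_list),
    modules = modules,
    intersection = obs$intersection,
    module_count = obs$module_count,
    null_intersection_sizes = null_sizes,
    fold_enrichment = fe,
    p = (r + 1) / (n_repeats + 1),
    per_gene_p = (gene_exceed + 1) / (n_repeats + 1),
    params = list(n_repeats = n_repeats, n_perm = n_perm, alpha = alpha,
                  min_size = min_size, universe = universe, seed = seed)
  ), class = "pleiotropy_result")
}

#' @export
print.pleiotropy_result <- function(x, ...) {
  cat("pleiotropy_result over", length(x$diseases), "diseases\n")
  cat("  intersection:", length(x$intersection), "gene(s); p =",
      format(x$p, digits = 3), "\n")
  cat("  fold enrichment vs null:",
      if (is.na(x$fold_enrichment)) "undefined (null mean 0)"
      else format(x$fold_enrichment, digits = 3), "\n")
  invisible(x)
}

#' Annotation fraction as a function of module-count level
#'
#' For every level 0..D of the number of disease modules a gene belongs
#' to, computes the fraction of genes at that level carrying an
#' annotation, then the Pearson correlation between level and fraction.
#' Empty levels are skipped; a correlation needs at least three non-empty
#' levels. Constant fractions yield an undefined (NA) correlation.
#'
#' @param module_count Named integer vector, gene -> number of modules
#'   (genes of the universe absent from it count as level 0).
#' @param annotation Character vector of annotated genes.
#' @param universe Character vector, the full gene universe.
#' @param n_diseases Number of diseases D; defaults to `max(module_count)`.
#' @return A list with `level`, `fraction`, `n_genes`, `pcc`, and `p`.
#' @export
annotation_fraction_by_module_count <- function(module_count, annotation,
                                                universe,
                                                n_diseases = max(module_count)) {
  universe <- unique(as.character(universe))
  annotation <- unique(as.character(annotation))
  if (!all(annotation %in% universe)) {
    stop("annotation genes must lie in the universe", call. = FALSE)
  }
  if (!all(names(module_count) %in% universe)) {
    stop("module_count genes must lie in the universe", call. = FALSE)
  }
  counts <- integer(length(universe))
  names(counts) <- universe
  counts[names(module_count)] <- module_count
  levels <- 0:n_diseases
  n_genes <- vapply(levels, function(l) sum(counts == l), integer(1L))
  frac <- vapply(levels, function(l) {
    at <- counts == l
    if (!any(at)) return(NA_real_)
    mean(names(counts)[at] %in% annotation)
  }, numeric(1L))
  keep <- n_genes > 0L
  if (sum(keep) < 3L) {
    stop("fewer than 3 non-empty module-count levels; correlation undefined",
         call. = FALSE)
  }
  x <- levels[keep]; y <- frac[keep]
  if (stats::sd(y) == 0 || stats::sd(x) == 0) {
    pcc <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::cor.test(x, y, method = "pearson")
    pcc <- unname(ct$estimate); p <- ct$p.value
  }
  list(level = x, fraction = y, n_genes = n_genes[keep], pcc = pcc, p = p)
}
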