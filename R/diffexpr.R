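#' Construct an expression study
#'
#' Couples a features-by-samples expression matrix with a two-group
#' sample labelling (case/control). Feature identifiers are taken from
#' the matrix row names and must be unique.
#'
#' @param exprs Numeric matrix, rows = features (probes or genes),
#'   columns = samples; must have unique row names.
#' @param labels Character or factor of length `ncol(exprs)` with values
#'   `"case"` and `"control"` (or any two levels; the first level sorted
#'   alphabetically is the reference group).
#' @return An object of class `expression_study`: a list with `exprs`
#'   and `labels`.
#' @export
expression_study <- function(exprs, labels) {
  exprs <- as.matrix(exprs)
  if (!is.numeric(exprs)) stop("expression matrix must be numeric", call. = FALSE)
  if (anyNA(exprs)) stop("expression matrix contains missing values", call. = FALSE)
  if (is.null(rownames(exprs)) || anyDuplicated(rownames(exprs))) {
    stop("expression matrix needs unique row names (feature ids)", call. = FALSE)
  }
  labels <- as.factor(as.character(labels))
  if (length(labels) != ncol(exprs)) {
    stop("`labels` length must equal the number of samples", call. = FALSE)
  }
  if (nlevels(labels) != 2L) {
    stop("`labels` must have exactly two groups", call. = FALSE)
  }
  structure(list(exprs = exprs, labels = labels), class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", nrow(x$exprs), "features x", ncol(x$exprs),
      "samples (", paste(table(x$labels), levels(x$labels), collapse = ", "),
      ")\n")
  invisible(x)
}

#' Quantile-normalize an expression study
#'
#' Forces every sample (column) to share the same empirical distribution:
#' the mean of the column-wise sorted values. Ties within a column receive
#' the mean of their target quantile values. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param study An [expression_study()].
#' @return The study with a quantile-normalized matrix.
#' @export
quantile_normalize <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  study$exprs <- limma::normalizeQuantiles(study$exprs, ties = TRUE)
  study
}

#' Log2-transform an expression study
#'
#' @param study An [expression_study()].
#' @param offset Added before taking logs to guard zero intensities.
#' @return The study with `log2(exprs + offset)` values.
#' @export
log2_transform <- function(study, offset = 1) {
  stopifnot(inherits(study, "expression_study"))
  if (any(study$exprs + offset <= 0)) {
    stop("log transform undefined: values + offset must be positive", call. = FALSE)
  }
  study$exprs <- log2(study$exprs + offset)
  study
}

#' Collapse probe-level rows to genes by the median
#'
#' Maps probe identifiers to genes and summarizes multiple probes of the
#' same gene by their per-sample median. Probes without a mapping are
#' dropped with a message.
#'
#' @param study An [expression_study()] whose rows are probes.
#' @param probe_to_gene Named character vector: names are probe ids,
#'   values are gene ids. Each probe maps to at most one gene.
#' @return An [expression_study()] whose rows are genes.
#' @export
collapse_probes_median <- function(study, probe_to_gene) {
  stopifnot(inherits(study, "expression_study"))
  if (length(probe_to_gene) == 0L) stop("empty probe-to-gene mapping", call. = FALSE)
  if (is.null(names(probe_to_gene))) {
    stop("`probe_to_gene` must be a named vector (probe -> gene)", call. = FALSE)
  }
  if (anyDuplicated(names(probe_to_gene))) {
    stop("a probe maps to more than one gene", call. = FALSE)
  }
  probes <- rownames(study$exprs)
  gene <- unname(probe_to_gene[probes])
  unmapped <- is.na(gene)
  if (any(unmapped)) {
    message("dropping ", sum(unmapped), " unmapped probe(s)")
  }
  m <- study$exprs[!unmapped, , drop = FALSE]
  gene <- gene[!unmapped]
  if (nrow(m) == 0L) stop("no probes left after mapping", call. = FALSE)
  idx <- split(seq_len(nrow(m)), gene)
  out <- t(vapply(idx, function(i) {
    if (length(i) == 1L) m[i, ] else apply(m[i, , drop = FALSE], 2L, stats::median)
  }, numeric(ncol(m))))
  colnames(out) <- colnames(m)
  expression_study(out, study$labels)
}

#' Per-gene two-sample t-tests
#'
#' Computes pooled-variance two-sided two-sample t statistics for every
#' gene, comparing the two label groups. Zero-variance genes are assigned
#' t = 0 and p = 1 rather than dropped, so downstream gene universes stay
#' aligned with the network.
#'
#' @param study An [expression_study()] with at least two samples per group.
#' @return A `de_result` data frame with columns `gene`, `t`, `p`, `df`.
#' @export
per_gene_ttest <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  g1 <- study$labels == levels(study$labels)[1L]
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2L || n2 < 2L) {
    stop("need at least 2 samples per group (have ", n1, " and ", n2, ")",
         call. = FALSE)
  }
  m <- study$exprs
  x1 <- m[, g1, drop = FALSE]; x2 <- m[, !g1, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m2 - m1) / se
  zero <- se == 0
  t[zero] <- 0
  p <- 2 * stats::pt(-abs(t), df = df)
  p[zero] <- 1
  de_result(data.frame(gene = rownames(m), t = t, p = p, df = df,
                       row.names = NULL, stringsAsFactors = FALSE))
}

#' Validate / construct a differential-expression result table
#'
#' @param df Data frame with columns `gene`, `t`, `p` and optionally `df`.
#' @return The validated data frame with class `de_result`.
#' @export
de_result <- function(df) {
  stopifnot(is.data.frame(df), all(c("gene", "t", "p") %in% names(df)))
  if (anyDuplicated(df$gene)) stop("duplicate genes in DE result", call. = FALSE)
  if (any(!is.finite(df$t))) stop("non-finite t statistics", call. = FALSE)
  if (any(df$p <= 0 | df$p > 1)) {
    stop("P-values must lie in (0, 1]", call. = FALSE)
  }
  class(df) <- c("de_result", "data.frame")
  df
}

#' Mean squared t statistic of a gene set
#'
#' The set-level differential-expression statistic: the arithmetic mean of
#' squared per-gene t statistics over the set. For m independent null
#' genes with large group sizes, m times this statistic is approximately
#' chi-squared with m degrees of freedom, which makes effect sizes easy to
#' read; significance is nevertheless assessed by permutation
#' ([permutation_set_pvalue()]).
#'
#' @param de A `de_result`.
#' @param genes Non-empty character vector of genes present in `de`.
#' @return The mean of t^2 over `genes`.
#' @export
mean_squared_t <- function(de, genes) {
  stopifnot(inherits(de, "de_result"))
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop("empty gene set", call. = FALSE)
  idx <- match(genes, de$gene)
  if (anyNA(idx)) {
    stop("gene(s) missing from DE result: ",
         paste(utils::head(genes[is.na(idx)], 10L), collapse = ", "), call. = FALSE)
  }
  mean(de$t[idx]^2)
}

#' Permutation P-value for a gene-set statistic
#'
#' Assesses the [mean_squared_t()] statistic of a fixed gene set by
#' permuting sample group labels and recomputing the statistic, returning
#' the one-sided empirical P-value (r + 1) / (n_perm + 1) where r counts
#' permutations with a statistic at least as large as observed.
#'
#' @param study An [expression_study()].
#' @param genes Gene set, all present in the study.
#' @param n_perm Number of label permutations (>= 1).
#' @param seed Integer seed.
#' @return A list with `statistic` and `p`.
#' @export
permutation_set_pvalue <- function(study, genes, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(study, "expression_study"))
  if (!is.numeric(n_perm) || n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  n_perm <- as.integer(n_perm)
  genes <- unique(as.character(genes))
  missing <- setdiff(genes, rownames(study$exprs))
  if (length(genes) == 0L || length(missing) > 0L) {
    stop("gene set empty or genes missing from study", call. = FALSE)
  }
  sub <- study$exprs[genes, , drop = FALSE]
  lab <- study$labels
  stat_for <- function(l) {
    s <- expression_study(sub, l)
    de <- per_gene_ttest(s)
    mean(de$t^2)
  }
  observed <- stat_for(lab)
  null_stats <- numeric(n_perm)
  withr_seed(seed, {
    for (b in seq_len(n_perm)) {
      null_stats[b] <- stat_for(sample(lab))
    }
  })
  r <- sum(null_stats >= observed)
  list(statistic = observed, p = (r + 1) / (n_perm + 1))
}

#' Generalized-Pareto tail approximation of a permutation P-value
#'
#' Permutation tests cannot resolve P-values below 1 / (n + 1). When the
#' observed statistic lands in the extreme tail of the permutation null
#' (fewer than 10 exceedances), this routine fits a generalized Pareto
#' distribution (GPD) by maximum likelihood to the null exceedances above
#' the upper `tail_fraction` quantile and extrapolates
#' `p = tail_fraction * S_GPD(observed - threshold)`. Otherwise (or when
#' the fit degenerates) the empirical estimator (r + 1) / (n + 1) is
#' returned.
#'
#' @param null_statistics Numeric vector of permutation-null statistics.
#' @param observed Observed statistic (large = significant).
#' @param tail_fraction Fraction of the null used as tail exceedances,
#'   in (0, 0.5]; default 0.1 (threshold at the 90th percentile).
#' @return A single P-value.
#' @export
gpd_tail_pvalue <- function(null_statistics, observed, tail_fraction = 0.1) {
  stopifnot(length(null_statistics) >= 1, is.finite(observed))
  if (tail_fraction <= 0 || tail_fraction > 0.5) {
    stop("`tail_fraction` must lie in (0, 0.5]", call. = FALSE)
  }
  n <- length(null_statistics)
  r <- sum(null_statistics >= observed)
  empirical <- (r + 1) / (n + 1)
  if (r >= 10L) return(empirical)
  if (stats::sd(null_statistics) == 0) {
    warning("degenerate (constant) null distribution; returning empirical p")
    return(empirical)
  }
  thr <- stats::quantile(null_statistics, 1 - tail_fraction, names = FALSE)
  exc <- null_statistics[null_statistics > thr] - thr
  if (length(exc) < 5L || observed <= thr) return(empirical)
  fit <- fit_gpd(exc)
  if (is.null(fit)) {
    warning("GPD fit failed; returning empirical p")
    return(empirical)
  }
  p <- tail_fraction * gpd_survival(observed - thr, fit$scale, fit$shape)
  max(p, .Machine$double.xmin)
}

# Maximum-likelihood fit of a generalized Pareto distribution to
# exceedances. Parametrization: survival S(x) = (1 + shape * x / scale)^(-1/shape),
# shape -> 0 giving exp(-x / scale). Returns NULL on failure.
fit_gpd <- function(exc) {
  negll <- function(par) {
    scale <- exp(par[1L]); shape <- par[2L]
    z <- 1 + shape * exc / scale
    if (any(z <= 0)) return(1e10)
    if (abs(shape) < 1e-8) {
      length(exc) * log(scale) + sum(exc) / scale
    } else {
      length(exc) * log(scale) + (1 / shape + 1) * sum(log(z))
    }
  }
  init <- c(log(mean(exc)), 0.1)
  opt <- tryCatch(
    stats::optim(init, negll, method = "Nelder-Mead",
                 control = list(maxit = 2000)),
    error = function(e) NULL
  )
  if (is.null(opt) || opt$convergence != 0) return(NULL)
  list(scale = exp(opt$par[1L]), shape = opt$par[2L])
}

gpd_survival <- function(x, scale, shape) {
  if (x <= 0) return(1)
  if (abs(shape) < 1e-8) return(exp(-x / scale))
  z <- 1 + shape * x / scale
  if (z <= 0) return(if (shape < 0) 0 else 1)
  z^(-1 / shape)
}
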