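#' Construct a paired pre/post responder cohort
#'
#' @param pre,post Numeric genes-by-samples matrices with identical row
#'   and column names (pre- and post-treatment expression of the same
#'   subjects).
#' @param labels Character or factor of per-sample responder labels, two
#'   levels (conventionally `"HR"` and `"LR"`), at least 2 samples each.
#' @return An object of class `responder_cohort`.
#' @export
responder_cohort <- function(pre, post, labels) {
  pre <- as.matrix(pre); post <- as.matrix(post)
  if (!identical(dim(pre), dim(post)) ||
      !identical(rownames(pre), rownames(post)) ||
      !identical(colnames(pre), colnames(post))) {
    stop("`pre` and `post` must have identical genes and sample ids",
         call. = FALSE)
  }
  if (is.null(colnames(pre))) stop("matrices need sample ids as column names",
                                   call. = FALSE)
  labels <- as.factor(as.character(labels))
  if (length(labels) != ncol(pre)) {
    stop("`labels` length must equal the number of samples", call. = FALSE)
  }
  if (nlevels(labels) != 2L || any(table(labels) < 2L)) {
    stop("`labels` must have two groups with >= 2 samples each", call. = FALSE)
  }
  structure(list(pre = pre, post = post, labels = labels),
            class = "responder_cohort")
}

# Vectorized per-gene paired t statistics on a difference matrix.
paired_t_stats <- function(d) {
  n <- ncol(d)
  if (n < 2L) stop("need at least 2 sample pairs", call. = FALSE)
  md <- rowMeans(d)
  sd_d <- sqrt(rowSums((d - md)^2) / (n - 1))
  t <- md / (sd_d / sqrt(n))
  t[sd_d == 0 & md == 0] <- 0
  t[sd_d == 0 & md != 0] <- sign(md[sd_d == 0 & md != 0]) * Inf
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  p[is.infinite(t)] <- 0
  p[t == 0 & sd_d == 0] <- 1
  list(t = t, p = p, df = n - 1)
}

#' Genes differentially expressed by the treatment
#'
#' Selects genes whose paired pre-versus-post t-test (all samples pooled)
#' falls below `alpha`; the drug-responsive gene filter applied before
#' classifier construction.
#'
#' @param cohort A [responder_cohort()].
#' @param alpha Significance threshold; default 0.05.
#' @return Character vector of selected genes.
#' @export
drug_responsive_genes <- function(cohort, alpha = 0.05) {
  stopifnot(inherits(cohort, "responder_cohort"))
  res <- paired_t_stats(cohort$post - cohort$pre)
  rownames(cohort$pre)[res$p < alpha]
}

#' Restrict a gene set by disease-module membership
#'
#' Keeps genes belonging to at least `min_modules` disease modules, or —
#' in named-module mode — to one given module's gene set.
#'
#' @param genes Character vector of candidate genes.
#' @param module_count Named integer vector, gene -> number of modules.
#'   Genes absent from it count 0.
#' @param min_modules Minimum number of modules; 0 is the identity filter.
#' @param module Optional character vector: restrict to this module's
#'   genes instead of a count threshold.
#' @return The filtered gene set (possibly empty, with a warning).
#' @export
restrict_to_modules <- function(genes, module_count = NULL, min_modules = 2L,
                                module = NULL) {
  genes <- unique(as.character(genes))
  if (!is.null(module)) {
    out <- intersect(genes, module)
  } else {
    if (is.null(module_count)) stop("provide `module_count` or `module`",
                                    call. = FALSE)
    counts <- ifelse(genes %in% names(module_count),
                     module_count[genes], 0L)
    out <- genes[counts >= min_modules]
  }
  if (length(out) == 0L) warning("module restriction left no genes")
  out
}

# Common lambda grid: 100 points log-spaced from lambda_max (smallest
# penalty zeroing every coefficient) down to lambda_max * 1e-4.
lasso_lambda_grid <- function(X, y, nlambda = 100L, min_ratio = 1e-4) {
  yy <- as.numeric(y == levels(y)[2L])
  n <- length(yy)
  # standardize with the population SD, matching glmnet's internal scaling,
  # so grid[1] really zeroes every coefficient
  mu <- colMeans(X)
  s <- sqrt(colMeans(sweep(X, 2L, mu)^2))
  Xs <- sweep(sweep(X, 2L, mu), 2L, pmax(s, 1e-12), "/")
  lmax <- max(abs(crossprod(Xs, yy - mean(yy)))) / n * 1.000001
  lmax <- max(lmax, 1e-6)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = nlambda))
}

binomial_deviance <- function(y01, prob) {
  eps <- 1e-12
  prob <- pmin(pmax(prob, eps), 1 - eps)
  -2 * (y01 * log(prob) + (1 - y01) * log(1 - prob))
}

# glmnet warns whenever a binomial class has < 8 observations; responder
# cohorts are this small by design, so silence that specific warning.
quiet_glmnet <- function(...) {
  withCallingHandlers(
    glmnet::glmnet(...),
    warning = function(w) {
      msg <- conditionMessage(w)
      # path truncation on separable data is handled explicitly downstream
      if (grepl("fewer than 8", msg, fixed = TRUE) ||
          grepl("Convergence for .*lambda value", msg)) {
        invokeRestart("muffleWarning")
      }
    })
}

# Response probabilities for one sample across the whole lambda path,
# computed directly from the path object (no predict() dispatch).
path_probs <- function(fit, x) {
  eta <- fit$a0 + as.numeric(x %*% fit$beta)
  stats::plogis(eta)
}

#' L1-penalized logistic regression with leave-one-out penalty selection
#'
#' Fits the LASSO logistic path over a descending 100-point lambda grid
#' and selects the penalty minimizing the mean held-out binomial deviance
#' over leave-one-out folds, breaking ties toward the larger penalty
#' (sparser model). Predictors are standardized within each training fit
#' (glmnet's internal standardization).
#'
#' @param X Numeric samples-by-genes matrix (>= 4 samples).
#' @param y Two-level factor of sample labels; the second level is
#'   modelled as the positive class.
#' @param nlambda Grid size; default 100.
#' @param lambda_min_ratio Smallest penalty as a fraction of the
#'   all-zero penalty; default 1e-4.
#' @return A list with `lambda` (selected penalty), `coefficients`
#'   (named vector including `(Intercept)` from the full-data fit at the
#'   selected penalty), `lambda_grid`, and `cv_deviance`.
#' @export
fit_lasso_loocv <- function(X, y, nlambda = 100L, lambda_min_ratio = 1e-4) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 samples", call. = FALSE)
  if (nlevels(y) != 2L) stop("`y` must contain both classes", call. = FALSE)
  grid <- lasso_lambda_grid(X, y, nlambda, lambda_min_ratio)
  y01 <- as.numeric(y == levels(y)[2L])

  dev <- matrix(NA_real_, n, length(grid))
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (nlevels(droplevels(yi)) < 2L) next    # fold lost a class; skip
    fit <- quiet_glmnet(X[-i, , drop = FALSE], yi, family = "binomial",
                        lambda = grid, standardize = TRUE)
    pr <- path_probs(fit, X[i, ])
    # path may stop early; align by position
    dev[i, seq_along(pr)] <- binomial_deviance(y01[i], pr)
  }
  mean_dev <- colMeans(dev, na.rm = TRUE)
  best <- which(mean_dev <= min(mean_dev, na.rm = TRUE) + 1e-10)[1L]  # grid descends: first = largest lambda
  full <- quiet_glmnet(X, y, family = "binomial", lambda = grid,
                       standardize = TRUE)
  best <- min(best, length(full$lambda))   # full-data path may truncate earlier
  coefs <- c(full$a0[best], full$beta[, best])
  names(coefs) <- c("(Intercept)", rownames(full$beta))
  list(lambda = grid[best], coefficients = coefs, lambda_grid = grid,
       cv_deviance = mean_dev, fit = full)
}

#' Cross-validated responder probabilities
#'
#' Predicts each sample's probability of belonging to the positive class
#' (second factor level, conventionally HR) from a model fit entirely
#' without that sample: an outer leave-one-out loop in which the penalty
#' is re-selected by inner leave-one-out deviance within each training
#' fold. Calls are made at the 0.5 probability border.
#'
#' @inheritParams fit_lasso_loocv
#' @param genes_used Optional record of the gene set the matrix was
#'   restricted to (metadata only).
#' @return A `classifier_report`: list with `genes_used`, `lambda`
#'   (full-data selected penalty), `probabilities`, `calls`, `labels`,
#'   `n_correct`, and `permutation_p` (`NA` until
#'   [classifier_permutation_test()]).
#' @export
cv_probabilities <- function(X, y, nlambda = 100L, lambda_min_ratio = 1e-4,
                             genes_used = colnames(X)) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop("`y` must contain both classes", call. = FALSE)
  prob <- cv_prob_core(X, y, nlambda, lambda_min_ratio)
  pos <- levels(y)[2L]; neg <- levels(y)[1L]
  calls <- ifelse(prob > 0.5, pos, neg)
  full <- fit_lasso_loocv(X, y, nlambda, lambda_min_ratio)
  structure(list(genes_used = genes_used,
                 lambda = full$lambda,
                 probabilities = stats::setNames(prob, rownames(X)),
                 calls = stats::setNames(calls, rownames(X)),
                 labels = y,
                 n_correct = sum(calls == as.character(y)),
                 permutation_p = NA_real_),
            class = "classifier_report")
}

# Outer leave-one-out probabilities; the per-fold model and its inner
# lambda selection come from the same training fit, so the held-out
# sample never touches standardization, the path, or lambda choice.
cv_prob_core <- function(X, y, nlambda, lambda_min_ratio) {
  n <- nrow(X)
  prob <- numeric(n)
  for (i in seq_len(n)) {
    yi <- droplevels(y[-i])
    if (nlevels(yi) < 2L) { prob[i] <- mean(y[-i] == levels(y)[2L]); next }
    inner <- fit_lasso_loocv(X[-i, , drop = FALSE], yi, nlambda,
                             lambda_min_ratio)
    pp <- path_probs(inner$fit, X[i, ])
    best <- min(match(inner$lambda, inner$lambda_grid), length(pp))
    prob[i] <- pp[best]
  }
  prob
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("classifier_report:", x$n_correct, "/", length(x$labels),
      "correct cross-validated calls; lambda =",
      format(x$lambda, digits = 3))
  if (!is.na(x$permutation_p)) cat("; permutation p =",
                                   format(x$permutation_p, digits = 3))
  cat("\n")
  invisible(x)
}

#' Permutation test of classifier performance
#'
#' The statistic is the number of correct cross-validated calls (or the
#' summed cross-validated deviance, negated so larger is better). The
#' null reruns the complete cross-validation pipeline — including inner
#' penalty re-selection — on label permutations; P is
#' (r + 1) / (n_perm + 1).
#'
#' @inheritParams cv_probabilities
#' @param n_perm Number of label permutations (>= 1).
#' @param seed Integer seed.
#' @param statistic `"correct_calls"` (default) or `"deviance"`.
#' @return A `classifier_report` with `permutation_p` filled in.
#' @export
classifier_permutation_test <- function(X, y, n_perm = 1000L, seed = 1L,
                                        statistic = c("correct_calls",
                                                      "deviance"),
                                        nlambda = 100L,
                                        lambda_min_ratio = 1e-4) {
  statistic <- match.arg(statistic)
  if (!is.numeric(n_perm) || n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  n_perm <- as.integer(n_perm)
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  stat_of <- function(prob, labels) {
    if (statistic == "correct_calls") {
      sum((prob > 0.5) == (labels == levels(labels)[2L]))
    } else {
      y01 <- as.numeric(labels == levels(labels)[2L])
      -sum(binomial_deviance(y01, prob))
    }
  }
  report <- cv_probabilities(X, y, nlambda, lambda_min_ratio)
  observed <- stat_of(report$probabilities, y)
  null_stats <- numeric(n_perm)
  perms <- withr_seed(seed, replicate(n_perm, sample(seq_along(y)),
                                      simplify = FALSE))
  for (b in seq_len(n_perm)) {
    yb <- y[perms[[b]]]
    null_stats[b] <- stat_of(cv_prob_core(X, yb, nlambda, lambda_min_ratio), yb)
  }
  r <- sum(null_stats >= observed)
  report$permutation_p <- (r + 1) / (n_perm + 1)
  report
}

#' Per-group treatment perturbation
#'
#' Quantifies how strongly the treatment perturbed each responder group:
#' for each label, the mean over genes of the squared paired t statistic
#' between pre- and post-treatment expression within that group's
#' samples.
#'
#' @param cohort A [responder_cohort()].
#' @param genes Optional gene subset; default all genes.
#' @return Named numeric vector, one mean-squared-t value per label.
#' @export
group_perturbation <- function(cohort, genes = NULL) {
  stopifnot(inherits(cohort, "responder_cohort"))
  d <- cohort$post - cohort$pre
  if (!is.null(genes)) {
    genes <- unique(as.character(genes))
    if (!all(genes %in% rownames(d))) {
      stop("gene(s) missing from cohort", call. = FALSE)
    }
    d <- d[genes, , drop = FALSE]
  }
  vapply(levels(cohort$labels), function(l) {
    dl <- d[, cohort$labels == l, drop = FALSE]
    t <- paired_t_stats(dl)$t
    mean(t[is.finite(t)]^2)
  }, numeric(1L))
}
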