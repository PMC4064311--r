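test_that("quantile normalization forces common distributions and is idempotent", {
  m <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  st <- expression_study(m, c("case", "control"))
  qn <- quantile_normalize(st)
  expect_equal(unname(qn$exprs), matrix(c(2, 3, 2, 3), 2, 2))

  # identical columns are left unchanged
  m2 <- matrix(rep(c(5, 1, 3), 2), 3, 2,
               dimnames = list(paste0("g", 1:3), c("a", "b")))
  st2 <- expression_study(m2, c("case", "control"))
  expect_equal(quantile_normalize(st2)$exprs, st2$exprs)

  # a constant column receives the mean target value everywhere (tie rule)
  m3 <- cbind(a = c(1, 2, 3), b = c(7, 7, 7))
  rownames(m3) <- paste0("g", 1:3)
  st3 <- expression_study(m3, c("case", "control"))
  qn3 <- quantile_normalize(st3)
  expect_equal(unname(qn3$exprs[, "b"]), rep(mean(qn3$exprs[, "a"]), 3))

  # idempotency on random data
  st4 <- make_study(50, 4, 4, seed = 9)
  once <- quantile_normalize(st4)
  twice <- quantile_normalize(once)
  expect_equal(twice$exprs, once$exprs, tolerance = 1e-9)
})

test_that("probe collapse takes per-gene medians and drops unmapped probes", {
  m <- matrix(c(1, 3, 5, 2, 4, 6), 3, 2,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  st <- expression_study(m, c("case", "control"))
  map <- c(p1 = "GENE1", p2 = "GENE1", p3 = "GENE1")
  out <- collapse_probes_median(st, map)
  expect_equal(unname(out$exprs["GENE1", ]), c(3, 4))

  # single probe passes through; two probes average (even-count median)
  map2 <- c(p1 = "A", p2 = "B", p3 = "B")
  out2 <- collapse_probes_median(st, map2)
  expect_equal(unname(out2$exprs["A", ]), c(1, 2))
  expect_equal(unname(out2$exprs["B", ]), c(4, 5))

  map3 <- c(p1 = "A")
  expect_message(out3 <- collapse_probes_median(st, map3), "2 unmapped")
  expect_equal(rownames(out3$exprs), "A")

  expect_error(collapse_probes_median(st, character(0)), "empty")
})

test_that("per-gene t-tests match the pooled-variance oracle and its symmetries", {
  set.seed(4)
  st <- make_study(30, 3, 3, seed = 4)
  de <- per_gene_ttest(st)
  grp <- st$labels == "case"
  for (g in sample(rownames(st$exprs), 5)) {
    tt <- t.test(st$exprs[g, grp], st$exprs[g, !grp], var.equal = TRUE)
    expect_equal(abs(de$t[de$gene == g]), abs(unname(tt$statistic)))
    expect_equal(de$p[de$gene == g], tt$p.value)
    expect_equal(de$df[de$gene == g], unname(tt$parameter))
  }

  # flipping labels negates t, preserves p
  flipped <- expression_study(st$exprs,
                              ifelse(st$labels == "case", "control", "case"))
  de_f <- per_gene_ttest(flipped)
  expect_equal(de_f$t, -de$t)
  expect_equal(de_f$p, de$p)

  # identical groups and zero-variance genes
  m <- matrix(1, 2, 4, dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  m["g1", ] <- c(2, 3, 2, 3)
  de0 <- per_gene_ttest(expression_study(m, c("case", "case", "control", "control")))
  expect_equal(de0$t, c(0, 0))
  expect_equal(de0$p, c(1, 1))

  tiny <- expression_study(matrix(1:4, 1, 4, dimnames = list("g", paste0("s", 1:4))),
                           c("case", "control", "control", "control"))
  expect_error(per_gene_ttest(tiny), "2 samples")
})

test_that("per-gene p-values are uniform under the global null", {
  st <- make_study(2000, 10, 10, seed = 123)
  de <- per_gene_ttest(st)
  ks <- ks.test(de$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("mean squared t aggregates and approaches its chi-squared reference", {
  de <- de_result(data.frame(gene = c("a", "b", "c"), t = c(1, -1, 2),
                             p = c(0.5, 0.5, 0.1), df = 10))
  expect_equal(mean_squared_t(de, c("a", "b", "c")), 2.0)
  expect_equal(mean_squared_t(de, "c"), 4.0)
  expect_error(mean_squared_t(de, character(0)), "empty")
  expect_error(mean_squared_t(de, c("a", "zz")), "zz")
})

test_that("permutation set p-value detects planted shifts and ignores scale", {
  genes <- sprintf("g%03d", 1:10)
  st <- make_study(60, 10, 10, shift_genes = genes, shift = 2, seed = 31)
  res <- permutation_set_pvalue(st, genes, n_perm = 1000, seed = 7)
  expect_lte(res$p, 0.01)

  # invariant to positive rescaling of the matrix
  st_scaled <- expression_study(st$exprs * 7.3, st$labels)
  res2 <- permutation_set_pvalue(st_scaled, genes, n_perm = 200, seed = 5)
  res1 <- permutation_set_pvalue(st, genes, n_perm = 200, seed = 5)
  expect_equal(res1$p, res2$p)
  expect_equal(res1$statistic, res2$statistic)

  expect_error(permutation_set_pvalue(st, genes, n_perm = 0), "n_perm")
})

test_that("GPD tail approximation extends empirical p-values sensibly", {
  set.seed(10)
  nulls <- rexp(2000)

  # non-extreme observation: plain empirical estimator
  obs <- median(nulls)
  expect_equal(gpd_tail_pvalue(nulls, obs),
               (sum(nulls >= obs) + 1) / (length(nulls) + 1))

  # exponential tail: with only a few exceedances left, the GPD branch
  # engages and tracks the analytic survival exp(-x) within a factor of 2
  obs2 <- sort(nulls)[length(nulls) - 2] + 1e-9   # 2 exceedances remain
  p_gpd <- gpd_tail_pvalue(nulls, obs2)
  p_true <- exp(-obs2)
  expect_lt(p_gpd / p_true, 2)
  expect_gt(p_gpd / p_true, 0.5)

  # far beyond the largest null the estimate drops below the empirical
  # floor while staying positive
  p_far <- gpd_tail_pvalue(nulls, max(nulls) + 2)
  expect_lt(p_far, 1 / length(nulls))
  expect_gt(p_far, 0)

  # degenerate null falls back with a warning
  expect_warning(p_c <- gpd_tail_pvalue(rep(1, 100), 5), "degenerate")
  expect_equal(p_c, 1 / 101)

  expect_error(gpd_tail_pvalue(nulls, 1, tail_fraction = 0.9), "tail_fraction")
})
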