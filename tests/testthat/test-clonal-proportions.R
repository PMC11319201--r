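test_that("log2 fold change follows the stated pseudocount rule", {
  cc <- cluster_counts(tibble::tibble(
    cluster = c("eq", "half", "empty"),
    n_wt = c(30, 20, 8),
    n_variant = c(30, 10, 0)
  ), total_wt = 100, total_variant = 100)
  fc <- proportion_log2fc(cc)
  expect_equal(fc$log2fc[1], 0)
  expect_equal(fc$log2fc[2], -1)            # 10/100 vs 20/100
  expect_equal(fc$log2fc[3], log2(0.5 / 8.5))  # pseudocount on both sides
  expect_error(cluster_counts(tibble::tibble(cluster = "a", n_wt = 5,
                                             n_variant = 5),
                              total_wt = 3), "Totals")
})

test_that("permutation p matches exhaustive enumeration on a 6-cell instance", {
  # cluster A: 2 wt + 1 var; cluster B: 1 wt + 2 var
  cc <- cluster_counts(tibble::tibble(cluster = c("A", "B"),
                                      n_wt = c(2, 1), n_variant = c(1, 2)))
  # enumerate all C(6,3) = 20 choices of which pooled cells are "variant"
  cells <- c("A", "A", "A", "B", "B", "B")  # pooled cluster labels
  obs <- proportion_log2fc(cc)$log2fc
  null_A <- c(); null_B <- c()
  for (pick in utils::combn(6, 3, simplify = FALSE)) {
    nv <- c(sum(cells[pick] == "A"), sum(cells[pick] == "B"))
    nw <- c(3, 3) - nv
    zero <- nw == 0 | nv == 0
    fc <- log2(((nv + 0.5 * zero) / 3) / ((nw + 0.5 * zero) / 3))
    null_A <- c(null_A, abs(fc[1])); null_B <- c(null_B, abs(fc[2]))
  }
  exact <- c(mean(null_A >= abs(obs[1]) - 1e-12),
             mean(null_B >= abs(obs[2]) - 1e-12))

  n_iter <- 4000
  p_mc <- permutation_test(cc, n_iter = n_iter, seed = 5)$p.value
  mc_sd <- sqrt(exact * (1 - exact) / n_iter)
  expect_true(all(abs(p_mc - exact) <= 3 * mc_sd + 1 / n_iter))
})

test_that("permutation test is deterministic given a seed and add-one valid", {
  cc <- simulate_cluster_counts(c(a = 0.3, b = 0.7), log2fc = c(1, 0),
                                n_wt = 300, n_variant = 280, seed = 1)
  p1 <- permutation_test(cc, n_iter = 500, seed = 9)
  p2 <- permutation_test(cc, n_iter = 500, seed = 9)
  expect_identical(p1, p2)
  expect_true(all(p1$p.value >= 1 / 501))
})

test_that("exchanging condition labels negates log2FC and keeps p-values", {
  cc <- simulate_cluster_counts(c(a = 0.25, b = 0.35, c = 0.4),
                                log2fc = c(0.8, -0.5, 0),
                                n_wt = 400, n_variant = 350, seed = 2)
  swapped <- cluster_counts(
    tibble::tibble(cluster = cc$cluster, n_wt = cc$n_variant,
                   n_variant = cc$n_wt),
    total_wt = attr(cc, "total_variant"),
    total_variant = attr(cc, "total_wt"))
  a <- permutation_test(cc, n_iter = 400, seed = 7)
  b <- permutation_test(swapped, n_iter = 400, seed = 7)
  expect_equal(b$log2fc, -a$log2fc)
  expect_equal(b$p.value, a$p.value)
})

test_that("power grows with the planted shift at fixed n", {
  pvals <- vapply(c(0, 0.5, 1, 2), function(fc) {
    cc <- simulate_cluster_counts(c(a = 0.3, b = 0.7), log2fc = c(fc, 0),
                                  n_wt = 500, n_variant = 500, seed = 42)
    permutation_test(cc, n_iter = 500, seed = 8)$p.value[1]
  }, numeric(1))
  expect_true(all(diff(pvals) <= 0))
  expect_lt(pvals[4], 0.01)
})

test_that("bootstrap interval collapses for degenerate single-cluster data", {
  cc <- cluster_counts(tibble::tibble(cluster = "only", n_wt = 50,
                                      n_variant = 40))
  ci <- bootstrap_ci(cc, n_iter = 200, seed = 3)
  expect_equal(ci$conf.low, 0)
  expect_equal(ci$conf.high, 0)
})

test_that("bootstrap interval covers a known shift at nominal rate", {
  n_rep <- 200
  true_fc <- 1
  base <- c(a = 0.3, b = 0.7)
  var_props <- base * 2^c(true_fc, 0)
  var_props <- var_props / sum(var_props)
  target <- log2(var_props[1] / base[1])
  covered <- vapply(seq_len(n_rep), function(i) {
    cc <- simulate_cluster_counts(base, log2fc = c(true_fc, 0),
                                  n_wt = 800, n_variant = 800, seed = 1000 + i)
    ci <- bootstrap_ci(cc, n_iter = 300, seed = 2000 + i)
    ci$conf.low[1] <= target && target <= ci$conf.high[1]
  }, logical(1))
  # 95% nominal; allow Monte-Carlo slack for 200 replicates
  expect_gt(mean(covered), 0.88)
  expect_lt(mean(covered), 0.99)
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  # monotone nondecreasing in sorted p order and bounded by 1
  p <- c(0.001, 0.2, 0.03, 0.9, 0.04)
  adj <- fdr_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_true(all(adj <= 1 & adj >= p))
  expect_error(fdr_adjust(numeric(0)), "Empty")
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("full proportion analysis returns a coherent table", {
  cc <- simulate_cluster_counts(c(HSC = 0.2, Lym = 0.3, Mye = 0.5),
                                log2fc = c(0.5, -1, 0.2),
                                n_wt = 2000, n_variant = 1800, seed = 4)
  res <- test_cluster_proportions(cc, n_iter = 400, seed = 6)
  expect_true(all(res$conf.low <= res$log2fc & res$log2fc <= res$conf.high))
  expect_true(all(res$fdr >= res$p.value))
  expect_equal(res$fdr, fdr_adjust(res$p.value))
  plt <- ggplot2::autoplot(res)
  expect_s3_class(plt, "ggplot")
})
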