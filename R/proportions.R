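#' Build a cluster-count table
#'
#' Per-cluster cell counts for the wild-type and variant conditions, plus the
#' QC-passing totals used as normalisation denominators (which may exceed the
#' sum of annotated cluster counts; the remainder is treated as an unassigned
#' stratum during resampling).
#'
#' @param counts Data frame with columns `cluster`, `n_wt`, `n_variant`.
#' @param total_wt,total_variant QC-passing totals per condition; default the
#'   column sums.
#' @return A tibble of class `cluster_counts` with totals stored as attributes.
#' @export
cluster_counts <- function(counts, total_wt = NULL, total_variant = NULL) {
  counts <- as_tibble(counts)
  if (!all(c("cluster", "n_wt", "n_variant") %in% names(counts))) {
    abort("`counts` needs columns `cluster`, `n_wt`, `n_variant`.")
  }
  if (any(counts$n_wt < 0 | counts$n_variant < 0)) {
    abort("Counts must be non-negative.")
  }
  total_wt <- total_wt %||% sum(counts$n_wt)
  total_variant <- total_variant %||% sum(counts$n_variant)
  if (total_wt < sum(counts$n_wt) || total_variant < sum(counts$n_variant)) {
    abort("Totals cannot be smaller than the summed cluster counts.")
  }
  if (total_wt < 1 || total_variant < 1) abort("Totals must be positive.")
  attr(counts, "total_wt") <- as.integer(total_wt)
  attr(counts, "total_variant") <- as.integer(total_variant)
  class(counts) <- unique(c("cluster_counts", class(counts)))
  counts
}

cc_totals <- function(counts) {
  list(wt = attr(counts, "total_wt") %||% sum(counts$n_wt),
       variant = attr(counts, "total_variant") %||% sum(counts$n_variant))
}

# log2 of the variant:wt proportion ratio; `pseudocount` is added to *both*
# counts of a cluster only when either of them is zero, leaving non-degenerate
# clusters untouched.
log2fc_from_counts <- function(n_wt, n_variant, total_wt, total_variant,
                               pseudocount = 0.5) {
  zero <- n_wt == 0 | n_variant == 0
  nw <- n_wt + pseudocount * zero
  nv <- n_variant + pseudocount * zero
  log2((nv / total_variant) / (nw / total_wt))
}

#' Per-cluster log2 fold change of cell proportions
#'
#' For each cluster, the log2 ratio of the variant-condition proportion to the
#' wild-type proportion, each normalised to its condition's QC-passing total.
#' A pseudocount (default 0.5) is added to both counts of a cluster only when
#' either count is zero, keeping empty clusters finite without perturbing the
#' rest.
#'
#' @param counts A [cluster_counts()] table (or plain data frame with the same
#'   columns).
#' @param pseudocount Value added to both counts when either is zero.
#' @return A tibble with `cluster`, `prop_wt`, `prop_variant`, `log2fc`.
#' @export
#' @examples
#' cc <- cluster_counts(data.frame(cluster = c("a", "b"),
#'                                 n_wt = c(20, 80), n_variant = c(10, 90)))
#' proportion_log2fc(cc)
proportion_log2fc <- function(counts, pseudocount = 0.5) {
  counts <- cluster_counts(counts, attr(counts, "total_wt"),
                           attr(counts, "total_variant"))
  tot <- cc_totals(counts)
  tibble(
    cluster = counts$cluster,
    prop_wt = counts$n_wt / tot$wt,
    prop_variant = counts$n_variant / tot$variant,
    log2fc = log2fc_from_counts(counts$n_wt, counts$n_variant,
                                tot$wt, tot$variant, pseudocount)
  )
}

# Draw `n_iter` multivariate-hypergeometric allocations of `k` cells to strata
# with sizes `pool` (sequential conditional binomial sampling). Returns a
# matrix strata x n_iter.
rmvhyper <- function(n_iter, pool, k) {
  n_strata <- length(pool)
  out <- matrix(0L, nrow = n_strata, ncol = n_iter)
  remaining_pool <- sum(pool)
  remaining_k <- rep.int(as.integer(k), n_iter)
  for (j in seq_len(n_strata - 1)) {
    x <- rhyper(n_iter, pool[j], remaining_pool - pool[j], remaining_k)
    out[j, ] <- x
    remaining_k <- remaining_k - x
    remaining_pool <- remaining_pool - pool[j]
  }
  out[n_strata, ] <- remaining_k
  out
}

#' Permutation test for per-cluster proportion differences
#'
#' Pools the cells of both conditions with their cluster labels (including an
#' unassigned stratum when the QC totals exceed the annotated counts), then
#' repeatedly reassigns condition labels at random while preserving the two
#' condition totals, recomputing the per-cluster log2 fold change each time.
#' The two-sided p-value per cluster is
#' \deqn{p = \frac{1 + \#\{|\mathrm{null}| \ge |\mathrm{obs}|\}}{1 + n_{iter}},}
#' the add-one form that can never be exactly zero.
#'
#' Label reassignment is sampled as a multivariate hypergeometric draw of one
#' condition's cells from the pooled cluster strata, which is equivalent to
#' shuffling individual cell labels. The drawn condition is the one with the
#' smaller total, so exchanging the two conditions (same seed) flips the sign
#' of every log2 fold change but reproduces identical p-values.
#'
#' @param counts A [cluster_counts()] table.
#' @param n_iter Number of label permutations (default 1000).
#' @param pseudocount Passed to the log2 fold-change computation.
#' @param seed Optional integer seed.
#' @return A tibble with `cluster`, `log2fc`, `p.value`.
#' @export
permutation_test <- function(counts, n_iter = 1000, pseudocount = 0.5,
                             seed = NULL) {
  counts <- cluster_counts(counts, attr(counts, "total_wt"),
                           attr(counts, "total_variant"))
  check_count(n_iter, "n_iter")
  tot <- cc_totals(counts)
  obs <- log2fc_from_counts(counts$n_wt, counts$n_variant,
                            tot$wt, tot$variant, pseudocount)

  pool <- counts$n_wt + counts$n_variant
  unassigned <- (tot$wt + tot$variant) - sum(pool)
  pool_full <- c(pool, unassigned)
  k_clusters <- nrow(counts)

  # draw for the smaller condition so the test is label-exchange symmetric
  draw_variant <- tot$variant <= tot$wt
  k_draw <- if (draw_variant) tot$variant else tot$wt

  null_abs <- with_seed_if(seed, {
    alloc <- rmvhyper(n_iter, pool_full, k_draw)[seq_len(k_clusters), ,
                                                 drop = FALSE]
    if (draw_variant) {
      nv <- alloc
      nw <- pool - alloc
    } else {
      nw <- alloc
      nv <- pool - alloc
    }
    abs(log2fc_from_counts(nw, nv, tot$wt, tot$variant, pseudocount))
  })
  dim(null_abs) <- c(k_clusters, n_iter)

  p <- vapply(seq_len(k_clusters), function(j) {
    (1 + sum(null_abs[j, ] >= abs(obs[j]) - 1e-12)) / (1 + n_iter)
  }, numeric(1))

  tibble(cluster = counts$cluster, log2fc = obs, p.value = p)
}

#' Bootstrap confidence intervals for per-cluster log2 fold changes
#'
#' Resamples cells with replacement within each condition (over the cluster
#' strata plus any unassigned remainder), recomputes the per-cluster log2
#' fold change, and reports the percentile 95% interval.
#'
#' @inheritParams permutation_test
#' @param conf Interval coverage (default 0.95).
#' @return A tibble with `cluster`, `log2fc`, `conf.low`, `conf.high`.
#' @export
bootstrap_ci <- function(counts, n_iter = 1000, pseudocount = 0.5,
                         conf = 0.95, seed = NULL) {
  counts <- cluster_counts(counts, attr(counts, "total_wt"),
                           attr(counts, "total_variant"))
  check_count(n_iter, "n_iter")
  tot <- cc_totals(counts)
  obs <- log2fc_from_counts(counts$n_wt, counts$n_variant,
                            tot$wt, tot$variant, pseudocount)
  k <- nrow(counts)
  probs_wt <- c(counts$n_wt, tot$wt - sum(counts$n_wt)) / tot$wt
  probs_var <- c(counts$n_variant, tot$variant - sum(counts$n_variant)) /
    tot$variant

  boot <- with_seed_if(seed, {
    bw <- rmultinom(n_iter, tot$wt, probs_wt)[seq_len(k), , drop = FALSE]
    bv <- rmultinom(n_iter, tot$variant, probs_var)[seq_len(k), , drop = FALSE]
    log2fc_from_counts(bw, bv, tot$wt, tot$variant, pseudocount)
  })
  dim(boot) <- c(k, n_iter)
  alpha <- (1 - conf) / 2
  ci <- t(apply(boot, 1, quantile, probs = c(alpha, 1 - alpha), names = FALSE))

  tibble(cluster = counts$cluster, log2fc = obs,
         conf.low = ci[, 1], conf.high = ci[, 2])
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjustment with monotonicity enforcement, delegated to
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0) abort("Empty p-value vector.")
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Full per-cluster proportion analysis
#'
#' Convenience wrapper running [proportion_log2fc()], [permutation_test()],
#' [bootstrap_ci()] and [fdr_adjust()] in one call, mirroring the summary
#' table a cluster-proportion figure reports.
#'
#' @inheritParams permutation_test
#' @param conf Bootstrap interval coverage.
#' @return A tibble of class `proportion_result`: `cluster`, `prop_wt`,
#'   `prop_variant`, `log2fc`, `conf.low`, `conf.high`, `p.value`, `fdr`.
#' @export
#' @examples
#' cc <- simulate_cluster_counts(c(a = 0.3, b = 0.7), log2fc = c(-1, 0),
#'                               n_wt = 2000, n_variant = 2000, seed = 1)
#' test_cluster_proportions(cc, n_iter = 200, seed = 2)
test_cluster_proportions <- function(counts, n_iter = 1000, pseudocount = 0.5,
                                     conf = 0.95, seed = NULL) {
  base <- proportion_log2fc(counts, pseudocount)
  perm <- permutation_test(counts, n_iter, pseudocount, seed = seed)
  boot <- bootstrap_ci(counts, n_iter, pseudocount, conf = conf,
                       seed = if (is.null(seed)) NULL else seed + 1L)
  out <- dplyr::left_join(base, dplyr::select(boot, "cluster", "conf.low",
                                              "conf.high"), by = "cluster")
  out <- dplyr::left_join(out, dplyr::select(perm, "cluster", "p.value"),
                          by = "cluster")
  out$fdr <- fdr_adjust(out$p.value)
  class(out) <- c("proportion_result", class(out))
  out
}

#' @describeIn test_cluster_proportions Forest-style plot of per-cluster log2
#'   fold changes with bootstrap intervals; clusters passing `fdr < 0.05` are
#'   highlighted.
#' @param object A `proportion_result`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.proportion_result <- function(object, ...) {
  dat <- dplyr::mutate(object, significant = .data$fdr < 0.05)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log2fc, y = .data$cluster,
                                    colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (variant vs WT proportion)",
                  y = NULL, colour = "FDR < 0.05") +
    ggplot2::theme_minimal()
}
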