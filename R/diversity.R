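#' Pairwise difference distribution between X haplotypes
#'
#' Computes the Hamming distance (number of sites carrying different alleles)
#' for haplotype pairs and returns the distribution as a histogram tibble.
#' Two pairing modes reflect two readings of "any two X chromosomes":
#'
#' * `"all_pairs"` — every unordered pair among the H cohort haplotypes,
#'   including the two haplotypes of the same female: H(H-1)/2 pairs.
#' * `"within_individual"` — one pair per female, her two phased haplotypes:
#'   the diversity that X inactivation actually partitions into mutually
#'   exclusive clonal compartments inside one body.
#'
#' @param hm A [haplotype_matrix()], typically after [filter_sites()].
#' @param mode Pairing mode; see above.
#'
#' @return A tibble of class `pairwise_diff_dist` with columns `differences`
#'   and `n_pairs`, ordered by `differences`, plus attributes `mode`,
#'   `n_pairs_total` and `n_haplotypes`.
#' @export
#' @examples
#' geno <- rbind(c(0, 0, 0), c(0, 1, 1), c(1, 0, 1), c(1, 1, 0))
#' hm <- haplotype_matrix(
#'   geno,
#'   tibble::tibble(chrom = "chrX", pos = 1:3, ref = "A", alt = "G"),
#'   tibble::tibble(haplotype = c("f1_hap1", "f1_hap2", "f2_hap1", "f2_hap2"),
#'                  sample = rep(c("f1", "f2"), each = 2),
#'                  sex = "female", hap_index = rep(1:2, 2))
#' )
#' pairwise_differences(hm)  # all six pairs differ at exactly two sites
pairwise_differences <- function(hm, mode = c("all_pairs", "within_individual")) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  mode <- match.arg(mode)
  geno <- hm$geno
  H <- nrow(geno)

  if (mode == "all_pairs") {
    if (H < 2) abort("All-pairs mode needs at least 2 haplotypes.")
    d <- if (ncol(geno) == 0) {
      rep(0, H * (H - 1) / 2)
    } else {
      # Manhattan distance on a 0/1 matrix is the Hamming distance
      as.vector(dist(geno, method = "manhattan"))
    }
  } else {
    fem <- hm$haplotypes[hm$haplotypes$sex == "female", , drop = FALSE]
    if (nrow(fem) == 0) abort("Within-individual mode needs at least 1 female.")
    by_sample <- split(seq_len(H)[hm$haplotypes$sex == "female"], fem$sample)
    d <- vapply(by_sample, function(rows) {
      sum(geno[rows[1], ] != geno[rows[2], ])
    }, numeric(1))
  }

  d <- as.integer(round(d))
  hist <- dplyr::count(tibble(differences = d), .data$differences,
                       name = "n_pairs")
  structure(hist,
            mode = mode,
            n_pairs_total = length(d),
            n_haplotypes = H,
            class = c("pairwise_diff_dist", class(hist)))
}

#' Closed-form mean pairwise difference from allele counts
#'
#' Independent route to the all-pairs mean: a site where `c` of `H`
#' haplotypes carry the alternate allele contributes `c * (H - c)` discordant
#' pairs, so the mean over all C(H,2) pairs is
#' \deqn{\bar d = \sum_s c_s (H - c_s) / \binom{H}{2}.}
#' Exactly equals the mean of [pairwise_differences()] in all-pairs mode;
#' used as a cross-check oracle in the test suite.
#'
#' @param hm A [haplotype_matrix()].
#' @return The mean pairwise difference (numeric scalar).
#' @export
mean_pairwise_closed_form <- function(hm) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  H <- nrow(hm$geno)
  if (H < 2) abort("Need at least 2 haplotypes.")
  cs <- colSums(hm$geno)
  sum(cs * (H - cs)) / choose(H, 2)
}

#' Summarise a pairwise difference distribution
#'
#' Mean, range, quantiles and the fraction of pairs at or above a threshold.
#' Quantiles use the inverse-empirical-CDF rule (the smallest difference count
#' whose cumulative pair fraction reaches the probability), so a statement
#' like "90% of pairs carry at least q10 differences" is exactly decidable.
#'
#' @param dist A `pairwise_diff_dist` from [pairwise_differences()].
#' @param quantile_probs Probabilities for the quantile columns.
#' @param threshold Optional difference count; adds `frac_ge_threshold`, the
#'   fraction of pairs with at least this many differences.
#'
#' @return A one-row tibble: `n_pairs`, `mean`, `min`, `max`, one `q<p>`
#'   column per probability, and optionally `frac_ge_threshold`.
#' @export
summarize_diversity <- function(dist, quantile_probs = c(0.1, 0.5, 0.9),
                                threshold = NULL) {
  stopifnot(inherits(dist, "pairwise_diff_dist"))
  if (nrow(dist) == 0 || sum(dist$n_pairs) == 0) {
    abort("Empty difference distribution.")
  }
  total <- sum(dist$n_pairs)
  out <- tibble(
    n_pairs = total,
    mean = sum(dist$differences * dist$n_pairs) / total,
    min = min(dist$differences),
    max = max(dist$differences)
  )
  if (length(quantile_probs) > 0) {
    q <- histogram_quantile(dist$differences, dist$n_pairs, quantile_probs)
    names(q) <- paste0("q", formatC(100 * quantile_probs, format = "fg"))
    out <- dplyr::bind_cols(out, as_tibble(as.list(q)))
  }
  if (!is.null(threshold)) {
    out$frac_ge_threshold <-
      sum(dist$n_pairs[dist$differences >= threshold]) / total
    out$threshold <- threshold
  }
  out
}

#' @describeIn pairwise_differences Histogram of the difference distribution.
#' @param object A `pairwise_diff_dist`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.pairwise_diff_dist <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$differences, y = .data$n_pairs)) +
    ggplot2::geom_col(width = 1, fill = "grey35") +
    ggplot2::labs(
      x = "missense differences per haplotype pair",
      y = "number of pairs",
      title = sprintf("Pairwise X-haplotype differences (%s)",
                      attr(object, "mode"))
    ) +
    ggplot2::theme_minimal()
}
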