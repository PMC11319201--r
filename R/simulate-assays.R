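# Simulators for the allele-specific assay inputs: qPCR CT panels with known
# clone fractions, cluster counts with known per-cluster shifts, and ranked
# expression matrices with a planted gene-set signal.

#' Simulate an allele-specific qPCR panel with known clone fractions
#'
#' Generates per-replicate threshold-cycle (CT) pairs for the wild-type and
#' variant probes of each sample. The CT difference follows the logit model
#' used throughout the package,
#' \deqn{\Delta C_T = C_{T,var} - C_{T,wt} = \delta - \log_E\!\frac{f}{1-f} + \epsilon,}
#' where `f` is the true variant-clone fraction, `E` the amplification
#' efficiency (fold per cycle), `delta` the calibration offset (the
#' \eqn{\Delta C_T} of a 50:50 mixture) and \eqn{\epsilon} i.i.d. Gaussian
#' per-well noise in cycles.
#'
#' @param fractions Named or unnamed numeric vector of true variant fractions,
#'   each strictly inside (0, 1): fractions of exactly 0 or 1 have infinite
#'   \eqn{\Delta C_T} under the model and are rejected.
#' @param n_replicates Replicates per sample.
#' @param efficiency Amplification efficiency `E` (> 1); 2 is perfect doubling.
#' @param delta Calibration offset in cycles.
#' @param noise_sd Per-well CT noise standard deviation in cycles.
#' @param baseline_ct Mean wild-type CT level (cosmetic; the analysis uses only
#'   the CT difference).
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `sample`, `tissue`, `replicate`, `ct_wt`,
#'   `ct_var` and attribute `truth` (tibble of sample, true_fraction).
#' @export
#' @examples
#' simulate_qpcr_panel(c(a = 0.5, b = 1/3), n_replicates = 2, noise_sd = 0)
simulate_qpcr_panel <- function(fractions, n_replicates = 3,
                                efficiency = 2, delta = 0,
                                noise_sd = 0.2, baseline_ct = 24,
                                seed = NULL) {
  if (length(fractions) < 1 || any(!is.finite(fractions))) {
    abort("`fractions` must be a non-empty numeric vector of finite values.")
  }
  if (any(fractions <= 0 | fractions >= 1)) {
    abort(paste0("All true fractions must lie strictly inside (0, 1): ",
                 "a pure 0 or 1 mixture has an infinite CT difference ",
                 "under the logit model and cannot be simulated."))
  }
  check_count(n_replicates, "n_replicates")
  if (efficiency <= 1) abort("`efficiency` must exceed 1 (fold per cycle).")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")

  ids <- names(fractions) %||% sprintf("S%03d", seq_along(fractions))
  with_seed_if(seed, {
    grid <- tidyr::expand_grid(sample = ids, replicate = seq_len(n_replicates))
    f <- fractions[match(grid$sample, ids)]
    dct_true <- delta - log(f / (1 - f), base = efficiency)
    ct_wt <- baseline_ct + rnorm(nrow(grid), 0, noise_sd)
    ct_var <- baseline_ct + dct_true + rnorm(nrow(grid), 0, noise_sd)
    out <- tibble(
      sample = grid$sample, tissue = "sim", replicate = grid$replicate,
      ct_wt = ct_wt, ct_var = ct_var
    )
    attr(out, "truth") <- tibble(sample = ids,
                                 true_fraction = unname(fractions))
    out
  })
}

#' Simulate per-cluster cell counts for two genotype conditions
#'
#' Draws cluster assignments multinomially for a wild-type and a variant
#' condition. The variant condition's cluster proportions are the baseline
#' proportions multiplied by `2^log2fc` per cluster and renormalised, so the
#' *intended* fold changes are known exactly (the renormalisation means the
#' realised marginal log2 fold change differs slightly from `log2fc` unless
#' the shifts cancel; the truth tibble records the renormalised expectation).
#'
#' @param base_props Baseline cluster proportions (must sum to 1 within 1e-9).
#'   Names become cluster labels.
#' @param log2fc Per-cluster log2 fold changes applied to the variant
#'   condition before renormalisation; recycled if length 1.
#' @param n_wt,n_variant Cells drawn for each condition (also used as the
#'   QC-passing totals).
#' @param seed Optional integer seed.
#'
#' @return A tibble of class `cluster_counts` with columns `cluster`, `n_wt`,
#'   `n_variant`, attributes `total_wt`, `total_variant`, and `truth` (tibble
#'   with the baseline and variant expected proportions and the expected
#'   log2 fold change after renormalisation).
#' @export
#' @examples
#' simulate_cluster_counts(c(HSC = 0.2, Lym = 0.3, Mye = 0.5),
#'                         log2fc = c(0, -1, 0.5),
#'                         n_wt = 6274, n_variant = 6073, seed = 1)
simulate_cluster_counts <- function(base_props, log2fc = 0,
                                    n_wt = 6274, n_variant = 6073,
                                    seed = NULL) {
  if (abs(sum(base_props) - 1) > 1e-9) {
    abort("`base_props` must sum to 1 (tolerance 1e-9).")
  }
  if (any(base_props < 0)) abort("`base_props` must be non-negative.")
  check_count(n_wt, "n_wt")
  check_count(n_variant, "n_variant")
  k <- length(base_props)
  log2fc <- rep_len(log2fc, k)
  labels <- names(base_props) %||% sprintf("cluster%02d", seq_len(k))

  var_props <- base_props * 2^log2fc
  var_props <- var_props / sum(var_props)

  with_seed_if(seed, {
    cw <- as.integer(rmultinom(1, n_wt, base_props))
    cv <- as.integer(rmultinom(1, n_variant, var_props))
    out <- tibble(cluster = labels, n_wt = cw, n_variant = cv)
    attr(out, "total_wt") <- as.integer(n_wt)
    attr(out, "total_variant") <- as.integer(n_variant)
    attr(out, "truth") <- tibble(
      cluster = labels,
      prop_wt = unname(base_props),
      prop_variant = unname(var_props),
      expected_log2fc = log2(unname(var_props) / unname(base_props))
    )
    class(out) <- c("cluster_counts", class(out))
    out
  })
}

#' Simulate an expression matrix with a planted gene-set signal
#'
#' Produces a genes-by-cells positive expression matrix in which a chosen
#' fraction of cells ("signal" cells) receive an additive boost on the genes
#' of `gene_set`, raising those genes' within-cell ranks. Background
#' expression is log-normal. Used to exercise the gene-set recovery-curve
#' scoring with known cell labels.
#'
#' @param n_cells,n_genes Matrix dimensions.
#' @param gene_set Character vector of gene names in the simulated universe
#'   (`g0001`, `g0002`, ...); must be non-empty.
#' @param signal_cells_fraction Fraction of cells carrying the signal.
#' @param signal_strength Additive boost applied to gene-set genes in signal
#'   cells, on the expression scale.
#' @param seed Optional integer seed.
#'
#' @return A list with `expression` (genes x cells matrix, dimnames set) and
#'   `cells` (tibble of cell, signal flag).
#' @export
simulate_ranked_expression <- function(n_cells, n_genes, gene_set,
                                       signal_cells_fraction = 0.5,
                                       signal_strength = 5,
                                       seed = NULL) {
  check_count(n_cells, "n_cells")
  check_count(n_genes, "n_genes")
  check_proportion(signal_cells_fraction, "signal_cells_fraction")
  if (length(gene_set) == 0) abort("`gene_set` must be non-empty.")
  genes <- sprintf("g%04d", seq_len(n_genes))
  if (!all(gene_set %in% genes)) {
    abort("`gene_set` contains genes outside the simulated universe.")
  }
  with_seed_if(seed, {
    expr <- matrix(rlnorm(n_genes * n_cells, meanlog = 0, sdlog = 1),
                   nrow = n_genes, ncol = n_cells,
                   dimnames = list(genes, sprintf("cell%04d", seq_len(n_cells))))
    n_signal <- round(signal_cells_fraction * n_cells)
    signal_cells <- if (n_signal > 0) sample(n_cells, n_signal) else integer(0)
    if (length(signal_cells) > 0) {
      expr[gene_set, signal_cells] <- expr[gene_set, signal_cells] + signal_strength
    }
    list(
      expression = expr,
      cells = tibble(cell = colnames(expr),
                     signal = seq_len(n_cells) %in% signal_cells)
    )
  })
}
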