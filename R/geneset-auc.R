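#' Gene-set recovery-curve score per cell
#'
#' An AUCell-style statistic: for each cell, genes are ranked by decreasing
#' expression (ties broken deterministically by gene order in the matrix) and
#' the score is the area under the step curve of cumulative gene-set members
#' recovered within the top `ceiling(top_fraction * n_genes)` ranks,
#' normalised by the maximum achievable area (all set genes at the very top).
#' Scores lie in \[0, 1\] and depend only on within-cell ranks, so any
#' strictly monotone transform of the expression values leaves them unchanged.
#'
#' @param expression Genes-by-cells numeric matrix with gene names as
#'   rownames.
#' @param gene_set Non-empty character vector of genes, all present in the
#'   matrix.
#' @param top_fraction Fraction of top-ranked genes scanned (default 0.05,
#'   the customary rank cutoff of this score family); in (0, 1].
#'
#' @return A tibble with `cell` and `auc`.
#' @export
#' @examples
#' m <- matrix(c(5, 4, 3, 2, 1), ncol = 1,
#'             dimnames = list(paste0("g", 1:5), "cell1"))
#' gene_set_auc(m, c("g1", "g2"), top_fraction = 0.4)  # set fills the top: 1
gene_set_auc <- function(expression, gene_set, top_fraction = 0.05) {
  if (length(gene_set) == 0) abort("`gene_set` must be non-empty.")
  if (is.null(rownames(expression))) {
    abort("`expression` must carry gene names as rownames.")
  }
  if (!all(gene_set %in% rownames(expression))) {
    abort("All `gene_set` genes must be present in the expression matrix.")
  }
  if (top_fraction <= 0 || top_fraction > 1) {
    abort("`top_fraction` must lie in (0, 1].")
  }
  expression <- as.matrix(expression)
  n_genes <- nrow(expression)
  k <- as.integer(ceiling(top_fraction * n_genes))
  in_set <- rownames(expression) %in% gene_set
  n_set <- sum(in_set)
  max_area <- sum(pmin(seq_len(k), n_set))

  auc <- vapply(seq_len(ncol(expression)), function(j) {
    # decreasing expression, ties resolved by stable gene index
    ord <- order(-expression[, j], seq_len(n_genes))
    hits <- in_set[ord[seq_len(k)]]
    sum(cumsum(hits)) / max_area
  }, numeric(1))

  tibble(cell = colnames(expression) %||% as.character(seq_along(auc)),
         auc = auc)
}

#' Classify cells as gene-set positive by score threshold
#'
#' Inclusive threshold on the recovery-curve score: a cell whose score equals
#' the threshold is classified positive. The default 0.2 is the cutoff used
#' to call advanced lineage-primed cells.
#'
#' @param scores Output of [gene_set_auc()] (or a numeric vector of scores).
#' @param threshold Score cutoff in \[0, 1\].
#' @return The input tibble with a logical `positive` column (or a logical
#'   vector for numeric input).
#' @export
classify_primed <- function(scores, threshold = 0.2) {
  check_proportion(threshold, "threshold")
  if (is.numeric(scores)) {
    if (any(scores < 0 | scores > 1)) abort("Scores must lie in [0, 1].")
    return(scores >= threshold)
  }
  scores <- as_tibble(scores)
  if (any(scores$auc < 0 | scores$auc > 1)) abort("Scores must lie in [0, 1].")
  dplyr::mutate(scores, positive = .data$auc >= threshold)
}
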