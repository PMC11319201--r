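# Builders for small in-memory fixtures shared across the test files.

# The canonical 4-haplotype / 3-site worked example: 000, 011, 101, 110.
# Every one of the 6 unordered pairs differs at exactly 2 sites.
toy_hm <- function() {
  geno <- rbind(c(0, 0, 0), c(0, 1, 1), c(1, 0, 1), c(1, 1, 0))
  haplotype_matrix(
    geno,
    tibble::tibble(chrom = "chrX", pos = c(101L, 202L, 303L),
                   ref = "A", alt = "G",
                   gene = c("G1", "G1", "G2"),
                   consequence = c("missense", "missense", "synonymous")),
    tibble::tibble(
      haplotype = c("f1_hap1", "f1_hap2", "f2_hap1", "f2_hap2"),
      sample = rep(c("f1", "f2"), each = 2),
      sex = "female", hap_index = rep(1:2, 2))
  )
}

# Random cohort matrix with n_f females and n_m males over s sites.
random_hm <- function(n_f, n_m, s, seed) {
  withr::with_seed(seed, {
    H <- 2L * n_f + n_m
    af <- stats::rbeta(s, 0.3, 1.5)
    geno <- matrix(stats::rbinom(H * s, 1, rep(af, each = H)), nrow = H)
    samples <- c(rep(sprintf("F%03d", seq_len(n_f)), each = 2),
                 sprintf("M%03d", seq_len(n_m)))
    haplotype_matrix(
      geno,
      tibble::tibble(chrom = "chrX", pos = seq_len(s) * 10L,
                     ref = "A", alt = "G"),
      tibble::tibble(
        haplotype = paste0(samples, "_", c(rep(1:2, n_f), rep(1L, n_m))),
        sample = samples,
        sex = c(rep("female", 2 * n_f), rep("male", n_m)),
        hap_index = c(rep(1:2, n_f), rep(1L, n_m)))
    )
  })
}

# Naive per-pair Hamming loop, the independent oracle for the dist() path.
brute_force_pair_distances <- function(geno) {
  H <- nrow(geno)
  d <- c()
  for (i in seq_len(H - 1)) {
    for (j in (i + 1):H) {
      d <- c(d, sum(geno[i, ] != geno[j, ]))
    }
  }
  d
}

# Step-by-step recovery-curve area, the independent oracle for gene_set_auc().
brute_force_auc <- function(expr_col, gene_names, gene_set, top_fraction) {
  n <- length(expr_col)
  k <- ceiling(top_fraction * n)
  ord <- order(-expr_col, seq_len(n))
  area <- 0
  hits <- 0
  for (r in seq_len(k)) {
    if (gene_names[ord[r]] %in% gene_set) hits <- hits + 1
    area <- area + hits
  }
  max_area <- 0
  best <- 0
  for (r in seq_len(k)) {
    if (best < length(gene_set)) best <- best + 1
    max_area <- max_area + best
  }
  area / max_area
}

# Wilson score interval from its textbook closed form.
wilson_interval <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(centre - half, centre + half) / (1 + z^2 / n)
}

write_cluster_counts_tsv <- function(counts, path) {
  readr::write_tsv(tibble::as_tibble(counts), path, progress = FALSE)
  path
}
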