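#' Configuration for a synthetic phased chrX cohort
#'
#' Bundles and validates the parameters of [simulate_cohort()]. The defaults
#' emulate a large reference cohort: 1,271 XX and 1,233 XY donors (3,775 X
#' haplotypes in total), 13,796 segregating coding sites, a U-shaped-left
#' allele-frequency spectrum, a roughly 2:1 missense:synonymous split of
#' coding variants and about 20% of genes escaping X inactivation.
#'
#' @param n_females,n_males Number of XX / XY donors (each female contributes
#'   two X haplotypes, each male one).
#' @param n_sites Number of biallelic SNV sites to simulate.
#' @param af_shape_a,af_shape_b Shape parameters of the Beta distribution from
#'   which per-site alternate-allele frequencies are drawn; the default
#'   (0.2, 2) concentrates mass at rare alleles as empirical site-frequency
#'   spectra do.
#' @param frac_missense Proportion of sites labelled missense (the remainder
#'   are synonymous).
#' @param frac_escape_genes Proportion of genes flagged as escaping X
#'   inactivation.
#' @param n_genes Number of non-overlapping genes; sites are assigned to genes
#'   in contiguous blocks.
#' @param seed Integer seed controlling all randomness of the cohort draw.
#'
#' @return A list of class `cohort_sim_config`.
#' @export
#' @examples
#' cohort_sim_config(n_females = 5, n_males = 3, n_sites = 50, n_genes = 5, seed = 1)
cohort_sim_config <- function(n_females = 1271, n_males = 1233,
                              n_sites = 13796,
                              af_shape_a = 0.2, af_shape_b = 2,
                              frac_missense = 2 / 3,
                              frac_escape_genes = 0.2,
                              n_genes = 800, seed = 1L) {
  check_count(n_females, "n_females")
  check_count(n_males, "n_males")
  check_count(n_sites, "n_sites")
  check_count(n_genes, "n_genes")
  check_positive(af_shape_a, "af_shape_a")
  check_positive(af_shape_b, "af_shape_b")
  check_proportion(frac_missense, "frac_missense")
  check_proportion(frac_escape_genes, "frac_escape_genes")
  check_count(seed, "seed", min = 0)
  structure(
    list(n_females = as.integer(n_females), n_males = as.integer(n_males),
         n_sites = as.integer(n_sites),
         af_shape_a = af_shape_a, af_shape_b = af_shape_b,
         frac_missense = frac_missense,
         frac_escape_genes = frac_escape_genes,
         n_genes = as.integer(n_genes), seed = as.integer(seed)),
    class = "cohort_sim_config"
  )
}

#' Simulate a phased chrX cohort with known ground truth
#'
#' Draws a per-site alternate-allele frequency from a Beta distribution, then
#' draws every haplotype's allele independently at that frequency (sites are
#' unlinked). Writes the four files the diversity pipeline consumes — a phased
#' VCF, a sample panel TSV, a per-site consequence annotation TSV and a BED of
#' escape genes — and returns them together with the generating truth.
#'
#' Females receive phased diploid genotypes (`a|b`), males haploid genotypes
#' (`0`/`1`). Genes are contiguous, non-overlapping blocks of sites; escape
#' status is a per-gene property. The same `config` (including its seed)
#' always reproduces byte-identical files.
#'
#' @param config A [cohort_sim_config()].
#' @param out_dir Directory to write the files into (created if absent).
#'
#' @return A list of class `xclonal_cohort` with elements `vcf`, `panel`,
#'   `annotation`, `escape_bed` (file paths) and `truth`, a list carrying the
#'   drawn allele frequencies, site annotations (tibble), gene table (tibble
#'   with escape flags), and the haplotype-by-site 0/1 matrix.
#' @export
#' @examples
#' cfg <- cohort_sim_config(n_females = 3, n_males = 2, n_sites = 20,
#'                          n_genes = 4, seed = 7)
#' cohort <- simulate_cohort(cfg, out_dir = tempfile("cohort"))
#' dim(cohort$truth$haplotypes)  # 8 haplotypes x 20 sites
simulate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "cohort_sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  nf <- config$n_females; nm <- config$n_males
  ns <- config$n_sites; ng <- config$n_genes
  n_hap <- 2L * nf + nm

  truth <- with_seed_if(config$seed, {
    af <- rbeta(ns, config$af_shape_a, config$af_shape_b)
    consequence <- ifelse(stats::runif(ns) < config$frac_missense,
                          "missense", "synonymous")
    # contiguous gene blocks over the site index
    gene_id <- sort(rep_len(seq_len(ng), ns))
    gene_names <- sprintf("GENE%04d", seq_len(ng))
    escape <- stats::runif(ng) < config$frac_escape_genes
    geno <- matrix(rbinom(n_hap * ns, 1L, rep(af, each = n_hap)),
                   nrow = n_hap, ncol = ns)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, ns, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    list(af = af, consequence = consequence, gene_id = gene_id,
         gene_names = gene_names, escape = escape, geno = geno,
         ref = ref, alt = alt)
  })

  pos <- 100000L + seq_len(ns) * 150L
  sample_f <- sprintf("F%04d", seq_len(nf))
  sample_m <- sprintf("M%04d", seq_len(nm))
  samples <- c(sample_f, sample_m)

  # genotype strings: females phased diploid, males haploid
  gt_cols <- matrix("", nrow = ns, ncol = nf + nm)
  if (nf > 0) {
    a <- t(truth$geno[seq(1L, 2L * nf, by = 2L), , drop = FALSE])
    b <- t(truth$geno[seq(2L, 2L * nf, by = 2L), , drop = FALSE])
    gt_cols[, seq_len(nf)] <- paste0(a, "|", b)
  }
  if (nm > 0) {
    m <- t(truth$geno[2L * nf + seq_len(nm), , drop = FALSE])
    gt_cols[, nf + seq_len(nm)] <- as.character(m)
  }

  vcf_path <- file.path(out_dir, "cohort.vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=xclonal_simulate_cohort",
    "##contig=<ID=chrX>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(
    "chrX", pos, sprintf("site%05d", seq_len(ns)), truth$ref, truth$alt,
    ".", "PASS", ".", "GT",
    apply(gt_cols, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), vcf_path)

  panel_path <- file.path(out_dir, "panel.tsv")
  panel <- tibble(
    sample = samples,
    sex = c(rep("female", nf), rep("male", nm)),
    population = "SIM"
  )
  write_tsv_plain(panel, panel_path)

  sites <- tibble(
    chrom = "chrX", pos = pos, ref = truth$ref, alt = truth$alt,
    gene = truth$gene_names[truth$gene_id],
    consequence = truth$consequence
  )
  annot_path <- file.path(out_dir, "sites.tsv")
  write_tsv_plain(sites, annot_path)

  # BED (0-based half-open) covering the site span of each escape gene
  gene_span <- dplyr::summarise(
    dplyr::group_by(tibble(gene_id = truth$gene_id, pos = pos), .data$gene_id),
    start = min(.data$pos) - 1L, end = max(.data$pos), .groups = "drop"
  )
  esc_ids <- which(truth$escape)
  esc <- dplyr::filter(gene_span, .data$gene_id %in% esc_ids)
  bed_path <- file.path(out_dir, "escape.bed")
  writeLines(
    if (nrow(esc) > 0) {
      paste("chrX", esc$start, esc$end, truth$gene_names[esc$gene_id], sep = "\t")
    } else character(0),
    bed_path
  )

  hap_labels <- c(rbind(paste0(sample_f, "_hap1"), paste0(sample_f, "_hap2")),
                  sample_m)[seq_len(n_hap)]
  rownames(truth$geno) <- hap_labels

  structure(
    list(
      vcf = vcf_path, panel = panel_path, annotation = annot_path,
      escape_bed = bed_path,
      truth = list(
        allele_freq = truth$af,
        sites = dplyr::mutate(sites,
                              escape = truth$escape[truth$gene_id]),
        genes = tibble(gene = truth$gene_names,
                       escape = truth$escape),
        haplotypes = truth$geno
      ),
      config = config
    ),
    class = "xclonal_cohort"
  )
}
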