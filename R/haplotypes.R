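#' Construct a haplotype matrix
#'
#' The central container of the diversity analysis: a haplotypes-by-sites 0/1
#' matrix of alternate-allele carriage on chrX, with per-haplotype donor
#' provenance and per-site annotation. Females contribute two rows, males one.
#'
#' @param geno Integer/logical matrix (haplotypes x sites) of 0/1 alt carriage;
#'   no missing values.
#' @param sites Tibble with one row per site: at least `chrom`, `pos`, `ref`,
#'   `alt`; optionally `gene`, `consequence` (one of missense, synonymous,
#'   other).
#' @param haplotypes Tibble with one row per haplotype: `haplotype` (label),
#'   `sample`, `sex` ("female"/"male"), `hap_index` (1 or 2).
#'
#' @return An object of class `haplotype_matrix` with derived per-site
#'   `alt_count` and `freq` columns added to `sites`.
#' @export
haplotype_matrix <- function(geno, sites, haplotypes) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (anyNA(geno) || !all(geno %in% c(0L, 1L))) {
    abort("`geno` must be a complete 0/1 matrix (no missing entries).")
  }
  sites <- as_tibble(sites)
  haplotypes <- as_tibble(haplotypes)
  if (nrow(sites) != ncol(geno)) {
    abort("`sites` must have one row per column of `geno`.")
  }
  if (nrow(haplotypes) != nrow(geno)) {
    abort("`haplotypes` must have one row per row of `geno`.")
  }
  n_f <- length(unique(haplotypes$sample[haplotypes$sex == "female"]))
  n_m <- sum(haplotypes$sex == "male")
  if (nrow(geno) != 2L * n_f + n_m) {
    abort("Haplotype count must equal 2 x females + males.")
  }
  sites$alt_count <- as.integer(colSums(geno))
  sites$freq <- sites$alt_count / nrow(geno)
  structure(list(geno = geno, sites = sites, haplotypes = haplotypes),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<haplotype_matrix> %d haplotypes (%d females, %d males) x %d sites\n",
    nrow(x$geno),
    length(unique(x$haplotypes$sample[x$haplotypes$sex == "female"])),
    sum(x$haplotypes$sex == "male"), ncol(x$geno)))
  if ("consequence" %in% names(x$sites)) {
    tab <- table(x$sites$consequence)
    cat("  consequences:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.haplotype_matrix <- function(x) dim(x$geno)

parse_region <- function(region) {
  if (is.null(region)) return(NULL)
  m <- regmatches(region, regexec("^([^:]+)(?::([0-9]+)-([0-9]+))?$", region))[[1]]
  if (length(m) == 0) abort(sprintf("Cannot parse region '%s'.", region))
  list(chrom = m[2],
       start = if (nzchar(m[3])) as.integer(m[3]) else -Inf,
       end = if (nzchar(m[4])) as.integer(m[4]) else Inf)
}

read_bed_intervals <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character()))
  }
  parts <- strsplit(lines, "\t")
  tibble(
    chrom = vapply(parts, `[`, "", 1),
    start = as.integer(vapply(parts, `[`, "", 2)),
    end = as.integer(vapply(parts, `[`, "", 3)),
    name = vapply(parts, function(p) if (length(p) >= 4) p[4] else NA_character_, "")
  )
}

#' Load phased X haplotypes from a VCF and a sample panel
#'
#' Expands a phased chrX VCF into a [haplotype_matrix()]: two rows per female
#' (her phased haplotypes) and one per male (his single X). Multiallelic
#' records and non-SNVs are skipped with a message. Unphased female genotypes
#' are an error by default because haplotype identity is the whole point of
#' the downstream statistic; males may be written haploid (`0`/`1`) or as
#' homozygous diploid (`1|1`, `1/1`).
#'
#' @param vcf Path to a VCF v4.2 file (plain or bgzipped).
#' @param panel Path to a TSV with columns `sample`, `sex` (`female`/`male`),
#'   `population`, or a data frame of the same shape. Every VCF sample must
#'   appear here.
#' @param annotation Optional per-site annotation: TSV path or data frame with
#'   columns `chrom`, `pos`, `ref`, `alt`, `gene`, `consequence`. Attached to
#'   the site table for downstream filtering.
#' @param region Optional region string `"chrX"` or `"chrX:start-end"`
#'   (1-based inclusive) restricting the sites loaded.
#' @param par_mask Optional BED path (0-based half-open) of pseudoautosomal
#'   regions to exclude.
#' @param strict Error on unphased female genotypes (default). When `FALSE`
#'   an unphased heterozygote is still an error, but `a/a` homozygotes are
#'   accepted as trivially phased.
#' @param missing_policy How to treat missing genotypes: `"drop_site"`
#'   (default) removes the site cohort-wide, keeping the haplotype count
#'   constant at every retained site; `"error"` fails.
#'
#' @return A [haplotype_matrix()].
#' @export
read_phased_haplotypes <- function(vcf, panel, annotation = NULL,
                                   region = NULL, par_mask = NULL,
                                   strict = TRUE,
                                   missing_policy = c("drop_site", "error")) {
  missing_policy <- match.arg(missing_policy)
  panel_tab <- if (is.character(panel)) {
    read_tsv_strict(panel, c("sample", "sex"), "panel")
  } else {
    as_tibble(panel)
  }
  if (!all(panel_tab$sex %in% c("female", "male"))) {
    abort("panel `sex` must be 'female' or 'male'.")
  }

  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix_mat <- vcfR::getFIX(v)
  if (is.null(dim(fix_mat))) fix_mat <- t(as.matrix(fix_mat))  # single record
  fix <- as.data.frame(fix_mat, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt_raw)
  missing_panel <- setdiff(samples, panel_tab$sample)
  if (length(missing_panel) > 0) {
    abort(sprintf("VCF sample(s) missing from panel: %s",
                  paste(head(missing_panel, 5), collapse = ", ")))
  }
  sex <- panel_tab$sex[match(samples, panel_tab$sample)]

  pos <- as.integer(fix$POS)
  keep <- rep(TRUE, nrow(fix))

  reg <- parse_region(region)
  if (!is.null(reg)) {
    keep <- keep & fix$CHROM == reg$chrom & pos >= reg$start & pos <= reg$end
    if (!any(keep)) abort(sprintf("Region '%s' contains no records.", region))
  }

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  snv <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 & !multi
  n_skipped <- sum(keep & !snv)
  if (n_skipped > 0) {
    inform(sprintf("Skipped %d multiallelic or non-SNV record(s).", n_skipped))
  }
  keep <- keep & snv

  if (!is.null(par_mask)) {
    par <- read_bed_intervals(par_mask)
    in_par <- rep(FALSE, nrow(fix))
    for (i in seq_len(nrow(par))) {
      in_par <- in_par | (fix$CHROM == par$chrom[i] &
                            pos > par$start[i] & pos <= par$end[i])
    }
    if (any(keep & in_par)) {
      inform(sprintf("Excluded %d site(s) in pseudoautosomal mask.",
                     sum(keep & in_par)))
    }
    keep <- keep & !in_par
  }

  idx <- which(keep)
  if (length(idx) == 0) abort("No usable biallelic SNV records remain.")
  gt <- gt_raw[idx, , drop = FALSE]
  fix <- fix[idx, , drop = FALSE]
  pos <- pos[idx]

  n_f <- sum(sex == "female")
  hap_rows <- vector("list", length(samples))
  site_missing <- rep(FALSE, nrow(gt))

  for (j in seq_along(samples)) {
    g <- gt[, j]
    miss <- is.na(g) | g %in% c(".", "./.", ".|.")
    site_missing <- site_missing | miss
    g[miss] <- if (sex[j] == "female") "0|0" else "0"
    if (sex[j] == "female") {
      phased <- grepl("^[01]\\|[01]$", g)
      if (!strict) {
        # unphased homozygotes are trivially phased
        hom <- g %in% c("0/0", "1/1")
        g[hom] <- sub("/", "|", g[hom], fixed = TRUE)
        phased <- phased | hom
      }
      bad <- !phased
      if (any(bad)) {
        k <- which(bad)[1]
        abort(sprintf(
          "Unphased or malformed genotype '%s' for female sample %s at %s:%s.",
          gt[k, j], samples[j], fix$CHROM[k], pos[k]))
      }
      a <- as.integer(substr(g, 1, 1))
      b <- as.integer(substr(g, 3, 3))
      hap_rows[[j]] <- rbind(a, b)
    } else {
      hap <- integer(length(g))
      hap1 <- g %in% c("1", "1|1", "1/1")
      hap0 <- g %in% c("0", "0|0", "0/0")
      if (any(!hap0 & !hap1)) {
        k <- which(!hap0 & !hap1)[1]
        abort(sprintf(
          "Heterozygous or malformed genotype '%s' for male sample %s at %s:%s.",
          gt[k, j], samples[j], fix$CHROM[k], pos[k]))
      }
      hap[hap1] <- 1L
      hap_rows[[j]] <- rbind(hap)
    }
  }

  if (any(site_missing)) {
    if (missing_policy == "error") {
      abort(sprintf("%d site(s) have missing genotypes.", sum(site_missing)))
    }
    inform(sprintf("Dropped %d site(s) with missing genotypes.",
                   sum(site_missing)))
  }

  geno <- do.call(rbind, hap_rows)
  hap_meta <- dplyr::bind_rows(lapply(seq_along(samples), function(j) {
    if (sex[j] == "female") {
      tibble(haplotype = paste0(samples[j], "_hap", 1:2),
             sample = samples[j], sex = "female", hap_index = 1:2)
    } else {
      tibble(haplotype = samples[j], sample = samples[j],
             sex = "male", hap_index = 1L)
    }
  }))

  site_keep <- !site_missing
  sites <- tibble(
    chrom = fix$CHROM[site_keep], pos = pos[site_keep],
    ref = fix$REF[site_keep], alt = fix$ALT[site_keep]
  )
  geno <- geno[, site_keep, drop = FALSE]

  if (!is.null(annotation)) {
    ann <- if (is.character(annotation)) {
      read_tsv_strict(annotation,
                      c("chrom", "pos", "ref", "alt", "gene", "consequence"),
                      "annotation")
    } else {
      as_tibble(annotation)
    }
    sites <- dplyr::left_join(
      sites, dplyr::select(ann, "chrom", "pos", "ref", "alt",
                           "gene", "consequence"),
      by = c("chrom", "pos", "ref", "alt")
    )
  }
  rownames(geno) <- hap_meta$haplotype
  haplotype_matrix(geno, sites, hap_meta)
}

#' Filter haplotype-matrix sites by consequence and escape status
#'
#' Retains sites whose consequence class is in `keep_consequences` and whose
#' gene is not in the escape set. The canonical analysis keeps missense sites
#' and masks genes that escape X inactivation, since escape genes are
#' expressed from both X chromosomes and do not contribute to the diversity
#' between clonal compartments.
#'
#' @param hm A [haplotype_matrix()] whose sites carry `gene` and `consequence`
#'   annotation. Unannotated sites (NA consequence) are dropped with a warning.
#' @param keep_consequences Character vector of consequence classes to keep;
#'   `NULL` keeps all classes.
#' @param escape Escape genes to mask: a character vector of gene symbols, or
#'   a BED path whose 4th column names the genes. `NULL` masks nothing.
#'
#' @return A new, filtered [haplotype_matrix()]; the input is unmodified. The
#'   result may have zero sites.
#' @export
filter_sites <- function(hm, keep_consequences = "missense", escape = NULL) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  sites <- hm$sites
  keep <- rep(TRUE, nrow(sites))
  if (!is.null(keep_consequences)) {
    if (!"consequence" %in% names(sites)) {
      abort("Sites carry no `consequence` annotation; supply `annotation` when loading.")
    }
    unann <- is.na(sites$consequence)
    if (any(unann)) {
      warn(sprintf("Dropping %d unannotated site(s).", sum(unann)))
      keep <- keep & !unann
    }
    keep <- keep & sites$consequence %in% keep_consequences
  }
  if (!is.null(escape)) {
    esc_genes <- if (is.character(escape) && length(escape) == 1 &&
                       file.exists(escape)) {
      stats::na.omit(read_bed_intervals(escape)$name)
    } else {
      escape
    }
    if (!"gene" %in% names(sites)) {
      abort("Sites carry no `gene` annotation; cannot apply escape mask.")
    }
    keep <- keep & !(sites$gene %in% esc_genes)
  }
  haplotype_matrix(
    hm$geno[, keep, drop = FALSE],
    sites[keep, setdiff(names(sites), c("alt_count", "freq")), drop = FALSE],
    hm$haplotypes
  )
}
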