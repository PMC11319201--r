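# Stage runner: every analysis is invocable as a library call or through
# run_stage() with a flat config list, writing TSV/JSON results plus the fully
# resolved config and a provenance block, so shell and R usage give identical
# results.

stage_registry <- function() {
  list(
    simulate_cohort = stage_simulate_cohort,
    diversity = stage_diversity,
    skew_qpcr = stage_skew_qpcr,
    skew_counts = stage_skew_counts,
    proportions = stage_proportions,
    aucscore = stage_aucscore,
    founders_simulate = stage_founders_simulate,
    founders_estimate = stage_founders_estimate
  )
}

#' Run a named pipeline stage from a flat configuration
#'
#' Dispatches to one of the registered stages, validates its inputs first,
#' executes it, and writes a result bundle into `out_dir`: the stage's TSV and
#' JSON outputs, the fully resolved configuration (`config.json`, defaults
#' filled in) and a provenance block (`provenance.json` with package version
#' and a config hash). Identical configs yield identical config hashes, and
#' byte-identical outputs for deterministic stages.
#'
#' Stages and their config keys:
#' * `simulate_cohort` — n_females, n_males, n_sites, n_genes, af_shape_a,
#'   af_shape_b, frac_missense, frac_escape_genes, seed.
#' * `diversity` — vcf, panel, annotation, escape_bed, par_mask, region, mode
#'   (all_pairs/within_individual), keep_consequence, threshold,
#'   quantile_probs.
#' * `skew_qpcr` — measurements (TSV), calibration (TSV of fraction,
#'   delta_ct), efficiency, fit_efficiency, expected.
#' * `skew_counts` — counts (TSV with alt_reads/ref_reads), expected.
#' * `proportions` — counts (TSV cluster/n_wt/n_variant), total_wt,
#'   total_variant, n_iter, seed.
#' * `aucscore` — matrix (TSV genes x cells), gene_set (one symbol per line),
#'   top_fraction, threshold.
#' * `founders_simulate` — n_founders, n_individuals, p_active, tissue_cells,
#'   seed.
#' * `founders_estimate` — fractions (TSV with a fraction column), n_boot,
#'   seed.
#'
#' @param stage Stage name; see above.
#' @param config Named list of stage parameters (flat key-value).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with `stage`, `outputs` (named file paths),
#'   `config` (resolved), `config_hash`.
#' @export
run_stage <- function(stage, config = list(), out_dir) {
  reg <- stage_registry()
  if (!stage %in% names(reg)) {
    abort(sprintf("Unknown stage '%s'. Registered: %s.",
                  stage, paste(names(reg), collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- reg[[stage]](config, out_dir)
  resolved <- res$config
  hash <- rlang::hash(list(stage = stage, config = resolved))
  jsonlite::write_json(resolved, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  jsonlite::write_json(
    list(stage = stage,
         package = "xclonal",
         version = as.character(utils::packageVersion("xclonal")),
         config_hash = hash),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE
  )
  invisible(list(stage = stage, outputs = res$outputs,
                 config = resolved, config_hash = hash))
}

cfg_get <- function(config, key, default) {
  if (!is.null(config[[key]])) config[[key]] else default
}

cfg_require <- function(config, keys, stage) {
  missing <- keys[vapply(keys, function(k) is.null(config[[k]]), logical(1))]
  if (length(missing) > 0) {
    abort(sprintf("Stage '%s' requires config key(s): %s.",
                  stage, paste(missing, collapse = ", ")))
  }
}

stage_simulate_cohort <- function(config, out_dir) {
  cfg <- cohort_sim_config(
    n_females = cfg_get(config, "n_females", 1271),
    n_males = cfg_get(config, "n_males", 1233),
    n_sites = cfg_get(config, "n_sites", 13796),
    af_shape_a = cfg_get(config, "af_shape_a", 0.2),
    af_shape_b = cfg_get(config, "af_shape_b", 2),
    frac_missense = cfg_get(config, "frac_missense", 2 / 3),
    frac_escape_genes = cfg_get(config, "frac_escape_genes", 0.2),
    n_genes = cfg_get(config, "n_genes", 800),
    seed = cfg_get(config, "seed", 1L)
  )
  cohort <- simulate_cohort(cfg, out_dir)
  list(config = unclass(cfg),
       outputs = list(vcf = cohort$vcf, panel = cohort$panel,
                      annotation = cohort$annotation,
                      escape_bed = cohort$escape_bed))
}

stage_diversity <- function(config, out_dir) {
  cfg_require(config, c("vcf", "panel"), "diversity")
  resolved <- list(
    vcf = config$vcf, panel = config$panel,
    annotation = cfg_get(config, "annotation", NULL),
    escape_bed = cfg_get(config, "escape_bed", NULL),
    par_mask = cfg_get(config, "par_mask", NULL),
    region = cfg_get(config, "region", NULL),
    mode = cfg_get(config, "mode", "all_pairs"),
    keep_consequence = cfg_get(config, "keep_consequence", "missense"),
    threshold = cfg_get(config, "threshold", 101),
    quantile_probs = cfg_get(config, "quantile_probs", c(0.1, 0.5, 0.9))
  )
  validate_inputs(
    setNames(c(resolved$vcf, resolved$panel),
             c("vcf", "panel")), stop_on_fail = TRUE)
  hm <- read_phased_haplotypes(resolved$vcf, resolved$panel,
                               annotation = resolved$annotation,
                               region = resolved$region,
                               par_mask = resolved$par_mask)
  if (!is.null(resolved$annotation)) {
    hm <- filter_sites(hm, keep_consequences = resolved$keep_consequence,
                       escape = resolved$escape_bed)
  }
  d <- pairwise_differences(hm, mode = resolved$mode)
  summ <- summarize_diversity(d, quantile_probs = resolved$quantile_probs,
                              threshold = resolved$threshold)
  hist_path <- file.path(out_dir, "histogram.tsv")
  write_tsv_plain(as_tibble(d), hist_path)
  summ_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(as.list(summ), summ_path, auto_unbox = TRUE,
                       digits = NA)
  list(config = resolved,
       outputs = list(histogram = hist_path, summary = summ_path))
}

stage_skew_qpcr <- function(config, out_dir) {
  cfg_require(config, c("measurements", "calibration"), "skew_qpcr")
  resolved <- list(
    measurements = config$measurements, calibration = config$calibration,
    efficiency = cfg_get(config, "efficiency", 2),
    fit_efficiency = isTRUE(config$fit_efficiency),
    expected = cfg_get(config, "expected", 0.5)
  )
  meas <- read_tsv_strict(resolved$measurements,
                          c("sample", "replicate", "ct_wt", "ct_var"),
                          "qPCR measurements")
  calt <- read_tsv_strict(resolved$calibration, c("fraction", "delta_ct"),
                          "calibration")
  cal <- fit_calibration(calt, efficiency = resolved$efficiency,
                         fit_efficiency = resolved$fit_efficiency)
  fr <- quantify_qpcr(meas, cal)
  per_sample <- dplyr::summarise(dplyr::group_by(fr, .data$sample),
                                 fraction = mean(.data$fraction),
                                 .groups = "drop")
  test <- if (nrow(per_sample) >= 2) {
    tidy(test_skew(per_sample$fraction, expected = resolved$expected))
  } else {
    NULL
  }
  frac_path <- file.path(out_dir, "fractions.tsv")
  write_tsv_plain(fr, frac_path)
  test_path <- file.path(out_dir, "skew_test.json")
  jsonlite::write_json(
    list(calibration = list(efficiency = cal$efficiency, delta = cal$delta,
                            residual_sd = cal$residual_sd),
         test = if (is.null(test)) NULL else as.list(test)),
    test_path, auto_unbox = TRUE, null = "null", digits = NA)
  list(config = resolved,
       outputs = list(fractions = frac_path, skew_test = test_path))
}

stage_skew_counts <- function(config, out_dir) {
  cfg_require(config, "counts", "skew_counts")
  resolved <- list(counts = config$counts,
                   expected = cfg_get(config, "expected", 0.5))
  tab <- read_tsv_strict(resolved$counts, c("alt_reads", "ref_reads"),
                         "read counts")
  fr <- quantify_counts(tab)
  frac_path <- file.path(out_dir, "fractions.tsv")
  write_tsv_plain(fr, frac_path)
  test_path <- file.path(out_dir, "skew_test.json")
  test <- if (nrow(fr) >= 2) {
    as.list(tidy(test_skew(fr$fraction, expected = resolved$expected)))
  } else {
    NULL
  }
  jsonlite::write_json(list(test = test), test_path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  list(config = resolved,
       outputs = list(fractions = frac_path, skew_test = test_path))
}

stage_proportions <- function(config, out_dir) {
  cfg_require(config, "counts", "proportions")
  resolved <- list(
    counts = config$counts,
    total_wt = cfg_get(config, "total_wt", NULL),
    total_variant = cfg_get(config, "total_variant", NULL),
    n_iter = cfg_get(config, "n_iter", 1000),
    pseudocount = cfg_get(config, "pseudocount", 0.5),
    seed = cfg_get(config, "seed", NULL)
  )
  tab <- read_tsv_strict(resolved$counts, c("cluster", "n_wt", "n_variant"),
                         "cluster counts")
  cc <- cluster_counts(tab, resolved$total_wt, resolved$total_variant)
  res <- test_cluster_proportions(cc, n_iter = resolved$n_iter,
                                  pseudocount = resolved$pseudocount,
                                  seed = resolved$seed)
  res_path <- file.path(out_dir, "proportions.tsv")
  write_tsv_plain(as_tibble(res), res_path)
  list(config = resolved, outputs = list(proportions = res_path))
}

stage_aucscore <- function(config, out_dir) {
  cfg_require(config, c("matrix", "gene_set"), "aucscore")
  resolved <- list(
    matrix = config$matrix, gene_set = config$gene_set,
    top_fraction = cfg_get(config, "top_fraction", 0.05),
    threshold = cfg_get(config, "threshold", 0.2)
  )
  mat_tab <- readr::read_tsv(resolved$matrix, show_col_types = FALSE,
                             progress = FALSE)
  mat <- as.matrix(mat_tab[, -1, drop = FALSE])
  rownames(mat) <- mat_tab[[1]]
  gs <- readLines(resolved$gene_set)
  gs <- gs[nzchar(gs)]
  scores <- classify_primed(
    gene_set_auc(mat, gs, top_fraction = resolved$top_fraction),
    threshold = resolved$threshold
  )
  out_path <- file.path(out_dir, "scores.tsv")
  write_tsv_plain(scores, out_path)
  list(config = resolved, outputs = list(scores = out_path))
}

stage_founders_simulate <- function(config, out_dir) {
  cfg_require(config, c("n_founders", "n_individuals"), "founders_simulate")
  resolved <- list(
    n_founders = config$n_founders, n_individuals = config$n_individuals,
    p_active = cfg_get(config, "p_active", 0.5),
    tissue_cells = cfg_get(config, "tissue_cells", NULL),
    seed = cfg_get(config, "seed", NULL)
  )
  sim <- simulate_xci_cohort(resolved$n_founders, resolved$n_individuals,
                             p_active = resolved$p_active,
                             tissue_cells = resolved$tissue_cells,
                             seed = resolved$seed)
  out_path <- file.path(out_dir, "fractions.tsv")
  write_tsv_plain(as_tibble(sim), out_path)
  list(config = resolved, outputs = list(fractions = out_path))
}

stage_founders_estimate <- function(config, out_dir) {
  cfg_require(config, "fractions", "founders_estimate")
  resolved <- list(fractions = config$fractions,
                   n_boot = cfg_get(config, "n_boot", 1000),
                   seed = cfg_get(config, "seed", NULL))
  tab <- read_tsv_strict(resolved$fractions, "fraction", "fractions")
  fit <- estimate_founders(tab$fraction, n_boot = resolved$n_boot,
                           seed = resolved$seed)
  out_path <- file.path(out_dir, "founder_fit.json")
  jsonlite::write_json(as.list(tidy(fit)), out_path, auto_unbox = TRUE,
                       digits = NA)
  list(config = resolved, outputs = list(founder_fit = out_path))
}

#' Validate pipeline input files against their expected schemas
#'
#' Light-weight structural checks applied before any stage computes: the file
#' exists, has the expected header or record shape, and its first offending
#' record (if any) is reported. Inputs are never modified.
#'
#' Schemas: `vcf` (well-formed header and 8+ columns; multiallelic records are
#' counted as warnings, not failures), `panel` (sample/sex columns, sex in
#' female/male), `annotation`, `bed` (3+ columns, end > start), `qpcr`,
#' `cluster_counts`, `counts`, `fractions`.
#'
#' @param paths Named character vector or list: names are schema names, values
#'   file paths. Unnamed entries are guessed from the file extension.
#' @param stop_on_fail Abort on the first failing file (default `FALSE`:
#'   return the report).
#' @return A tibble with columns `file`, `schema`, `ok`, `message`.
#' @export
validate_inputs <- function(paths, stop_on_fail = FALSE) {
  paths <- as.list(paths)
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    abort("`paths` must be named by schema (vcf, panel, annotation, bed, ...).")
  }
  checkers <- list(
    vcf = check_vcf_file, panel = check_panel_file,
    annotation = check_annotation_file, bed = check_bed_file,
    qpcr = check_qpcr_file, cluster_counts = check_cluster_counts_file,
    counts = check_read_counts_file, fractions = check_fractions_file
  )
  rows <- purrr::imap(paths, function(path, schema) {
    if (!schema %in% names(checkers)) {
      return(tibble(file = path, schema = schema, ok = FALSE,
                    message = sprintf("unknown schema '%s'", schema)))
    }
    if (!file.exists(path)) {
      return(tibble(file = path, schema = schema, ok = FALSE,
                    message = "file not found"))
    }
    msg <- tryCatch(checkers[[schema]](path),
                    error = function(e) conditionMessage(e))
    tibble(file = path, schema = schema, ok = is.null(msg),
           message = msg %||% "ok")
  })
  report <- dplyr::bind_rows(rows)
  if (stop_on_fail && any(!report$ok)) {
    bad <- report[!report$ok, ][1, ]
    abort(sprintf("Input validation failed for %s (%s): %s",
                  bad$file, bad$schema, bad$message))
  }
  report
}

# Each checker returns NULL when the file passes, otherwise a message naming
# the first offending record.

check_vcf_file <- function(path) {
  lines <- readLines(path, n = 5000L)
  if (length(lines) == 0 || !startsWith(lines[1], "##fileformat=VCF")) {
    return("missing ##fileformat header line")
  }
  hdr <- which(startsWith(lines, "#CHROM"))
  if (length(hdr) == 0) return("missing #CHROM column header")
  body <- lines[-seq_len(hdr[1])]
  body <- body[nzchar(body)]
  n_multi <- 0L
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) {
      return(sprintf("record %d has %d columns (need >= 8)", i, length(f)))
    }
    if (grepl(",", f[5], fixed = TRUE)) n_multi <- n_multi + 1L
  }
  if (n_multi > 0) {
    warn(sprintf("%d multiallelic record(s) will be skipped at load time.",
                 n_multi))
  }
  NULL
}

check_panel_file <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("sample", "sex")) {
    if (!col %in% names(tab)) {
      return(sprintf("missing required column '%s'", col))
    }
  }
  bad <- which(!tab$sex %in% c("female", "male"))
  if (length(bad) > 0) {
    return(sprintf("row %d has sex '%s' (need female/male)",
                   bad[1], tab$sex[bad[1]]))
  }
  NULL
}

check_annotation_file <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    return(sprintf("missing required column(s): %s",
                   paste(missing, collapse = ", ")))
  }
  NULL
}

check_bed_file <- function(path) {
  iv <- read_bed_intervals(path)
  bad <- which(iv$end <= iv$start)
  if (length(bad) > 0) {
    return(sprintf("interval %d has end <= start (%s:%d-%d)",
                   bad[1], iv$chrom[bad[1]], iv$start[bad[1]], iv$end[bad[1]]))
  }
  NULL
}

check_qpcr_file <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample", "replicate", "ct_wt", "ct_var")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    return(sprintf("missing required column(s): %s",
                   paste(missing, collapse = ", ")))
  }
  bad <- which(!is.finite(tab$ct_wt) | !is.finite(tab$ct_var) |
                 tab$ct_wt <= 0 | tab$ct_var <= 0)
  if (length(bad) > 0) {
    return(sprintf("row %d has non-positive or non-finite CT", bad[1]))
  }
  NULL
}

check_cluster_counts_file <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("cluster", "n_wt", "n_variant")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    return(sprintf("missing required column(s): %s",
                   paste(missing, collapse = ", ")))
  }
  bad <- which(tab$n_wt < 0 | tab$n_variant < 0)
  if (length(bad) > 0) return(sprintf("row %d has negative count", bad[1]))
  NULL
}

check_read_counts_file <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("alt_reads", "ref_reads"), names(tab))
  if (length(missing) > 0) {
    return(sprintf("missing required column(s): %s",
                   paste(missing, collapse = ", ")))
  }
  NULL
}

check_fractions_file <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"fraction" %in% names(tab)) {
    return("missing required column 'fraction'")
  }
  bad <- which(tab$fraction < 0 | tab$fraction > 1)
  if (length(bad) > 0) {
    return(sprintf("row %d has fraction outside [0, 1]", bad[1]))
  }
  NULL
}
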