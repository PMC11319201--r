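# Shared input checks and small helpers.

# Run `expr` under a fixed RNG seed when one is supplied, otherwise use the
# current RNG stream. All exported stochastic functions funnel through here so
# that `seed` has one meaning package-wide.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    check_count(seed, "seed", min = 0)
    withr::with_seed(as.integer(seed), expr)
  }
}

check_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %s, not %s.",
                  name, min, deparse(substitute(x))[[1]]))
  }
  invisible(as.integer(x))
}

check_proportion <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single value in [0, 1].", name))
  }
  invisible(as.numeric(x))
}

check_positive <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name))
  }
  invisible(as.numeric(x))
}

# Weighted inverse-empirical-CDF quantile: the smallest value v whose
# cumulative weight fraction reaches p. Equivalent to quantile(type = 1) on
# the expanded sample, but works directly on a value/count histogram.
histogram_quantile <- function(values, counts, probs) {
  stopifnot(length(values) == length(counts), all(counts >= 0))
  ord <- order(values)
  values <- values[ord]
  cum <- cumsum(counts[ord]) / sum(counts)
  vapply(probs, function(p) {
    stopifnot(p >= 0, p <= 1)
    values[which(cum >= p - 1e-12)[1]]
  }, numeric(1))
}

read_tsv_strict <- function(path, required_cols, what) {
  if (!file.exists(path)) abort(sprintf("%s file not found: %s", what, path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required_cols, names(tab))
  if (length(missing) > 0) {
    abort(sprintf("%s file %s is missing required column(s): %s",
                  what, path, paste(missing, collapse = ", ")))
  }
  tab
}

write_tsv_plain <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
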