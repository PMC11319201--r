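#' Simulate clone fractions under the stochastic XCI founder model
#'
#' The null model for X-linked skew without selection: each of an individual's
#' `n_founders` founder cells independently inactivates one of its two X
#' chromosomes (keeping the other active with probability `p_active`, 0.5 by
#' default), and the clonal composition is fixed thereafter. The fraction of
#' clones with a given X active is then \eqn{K/N} with
#' \eqn{K \sim \mathrm{Binomial}(N, p)}, giving mean `p` and variance
#' \eqn{p(1-p)/N} (0.25/N under the fair null: skew from sampling alone).
#'
#' An optional second allocation layer draws `tissue_cells` of the N founders
#' without replacement (hypergeometrically) into a tissue, modelling the
#' allocation of founders to germ layers or tissues; the reported fraction is
#' then the tissue's. This layer can only add variance.
#'
#' @param n_founders Founder cells per individual (N >= 1).
#' @param n_individuals Number of individuals to simulate.
#' @param p_active Probability a founder keeps the focal X active; 0.5 is the
#'   unbiased null, other values model choice bias.
#' @param tissue_cells Optional second-layer sample size M, 1 <= M <=
#'   `n_founders`.
#' @param seed Optional integer seed.
#'
#' @return A tibble of class `skew_distribution` with one row per individual:
#'   `individual`, `fraction` (and `founder_fraction` when the tissue layer is
#'   active); attributes `n_founders`, `p_active`, `tissue_cells`.
#' @export
#' @examples
#' sim <- simulate_xci_cohort(n_founders = 8, n_individuals = 1000, seed = 1)
#' var(sim$fraction)  # close to 1/(4 * 8)
simulate_xci_cohort <- function(n_founders, n_individuals,
                                p_active = 0.5, tissue_cells = NULL,
                                seed = NULL) {
  check_count(n_founders, "n_founders")
  check_count(n_individuals, "n_individuals")
  check_proportion(p_active, "p_active")
  if (!is.null(tissue_cells)) {
    check_count(tissue_cells, "tissue_cells")
    if (tissue_cells > n_founders) {
      abort("`tissue_cells` cannot exceed `n_founders` (sampling without replacement).")
    }
  }
  out <- with_seed_if(seed, {
    k <- rbinom(n_individuals, n_founders, p_active)
    if (is.null(tissue_cells)) {
      tibble(individual = seq_len(n_individuals),
             fraction = k / n_founders)
    } else {
      kt <- rhyper(n_individuals, m = k, n = n_founders - k, k = tissue_cells)
      tibble(individual = seq_len(n_individuals),
             founder_fraction = k / n_founders,
             fraction = kt / tissue_cells)
    }
  })
  structure(out,
            n_founders = as.integer(n_founders),
            p_active = p_active,
            tissue_cells = if (is.null(tissue_cells)) NA_integer_
                           else as.integer(tissue_cells),
            class = c("skew_distribution", class(out)))
}

#' Estimate the founder-cell number from clone-fraction variance
#'
#' Method-of-moments inversion of the founder-sampling variance: under the
#' fair null the clone-fraction variance across individuals is 1/(4N), so
#' \deqn{\hat N = \frac{1}{4\,\widehat{\mathrm{Var}}},}
#' with the unbiased sample variance. A percentile bootstrap over individuals
#' gives the interval. Zero variance means the data carry no lower bound on N;
#' the estimate is flagged unbounded (infinite).
#'
#' @param fractions Numeric vector of per-individual clone fractions, or a
#'   data frame with a `fraction` column (e.g. [simulate_xci_cohort()]
#'   output).
#' @param n_boot Bootstrap replicates for the interval.
#' @param conf Interval coverage.
#' @param seed Optional integer seed.
#'
#' @return An object of class `founder_fit`: `n_hat` (unrounded),
#'   `n_hat_rounded`, `conf.low`, `conf.high`, `variance`, `n_individuals`,
#'   `unbounded` flag.
#' @export
estimate_founders <- function(fractions, n_boot = 1000, conf = 0.95,
                              seed = NULL) {
  if (is.data.frame(fractions)) fractions <- fractions$fraction
  fractions <- as.numeric(fractions)
  if (length(fractions) < 2) abort("Need at least 2 individuals.")
  if (any(fractions < 0 | fractions > 1)) {
    abort("Fractions must lie in [0, 1].")
  }
  check_count(n_boot, "n_boot")
  v <- var(fractions)
  n <- length(fractions)
  if (v == 0) {
    fit <- list(n_hat = Inf, n_hat_rounded = Inf,
                conf.low = Inf, conf.high = Inf,
                variance = 0, n_individuals = n, unbounded = TRUE)
    return(structure(fit, class = "founder_fit"))
  }
  n_hat <- 1 / (4 * v)
  boot <- with_seed_if(seed, {
    vapply(seq_len(n_boot), function(i) {
      vb <- var(fractions[sample.int(n, n, replace = TRUE)])
      if (vb == 0) Inf else 1 / (4 * vb)
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- quantile(boot, c(alpha, 1 - alpha), names = FALSE)
  structure(
    list(n_hat = n_hat, n_hat_rounded = round(n_hat),
         conf.low = ci[1], conf.high = ci[2],
         variance = v, n_individuals = n, unbounded = FALSE),
    class = "founder_fit"
  )
}

#' @export
print.founder_fit <- function(x, ...) {
  if (x$unbounded) {
    cat("<founder_fit> zero clone-fraction variance: founder number unbounded (Inf)\n")
  } else {
    cat(sprintf(
      "<founder_fit> N-hat = %.2f (~%d founders), 95%% CI [%.1f, %.1f], n = %d\n",
      x$n_hat, x$n_hat_rounded, x$conf.low, x$conf.high, x$n_individuals))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.founder_fit <- function(x, ...) {
  tibble(term = "n_founders", estimate = x$n_hat,
         conf.low = x$conf.low, conf.high = x$conf.high,
         unbounded = x$unbounded)
}

#' @exportS3Method generics::glance
glance.founder_fit <- function(x, ...) {
  tibble(variance = x$variance, n_individuals = x$n_individuals,
         n_hat = x$n_hat, unbounded = x$unbounded)
}

#' @describeIn simulate_xci_cohort Histogram of simulated clone fractions with
#'   the fair-XCI expectation marked.
#' @param object A `skew_distribution`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.skew_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fraction)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = attr(object, "p_active"),
                        linetype = 2, colour = "firebrick") +
    ggplot2::labs(
      x = "fraction of clones with the focal X active",
      y = "individuals",
      title = sprintf("Founder-sampling null (N = %d)",
                      attr(object, "n_founders"))
    ) +
    ggplot2::theme_minimal()
}
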