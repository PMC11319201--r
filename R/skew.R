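#' Fit an allele-specific qPCR calibration model
#'
#' Allele-specific TaqMan probes report the variant:wild-type mRNA ratio as a
#' threshold-cycle difference. The package models
#' \deqn{\Delta C_T = \delta - \log_E\!\frac{f}{1-f},}
#' with `f` the variant fraction, `E` the amplification efficiency (fold per
#' cycle) and `delta` the offset absorbing probe-specific normalisation (the
#' \eqn{\Delta C_T} observed at a 50:50 mixture). Calibration mixtures with
#' known `f` identify `delta` (and optionally `E`).
#'
#' With `E` fixed the fit is the exact least-squares intercept: `delta` is the
#' mean of \eqn{\Delta C_T + \log_E(f/(1-f))} over the mixtures. With
#' `fit_efficiency = TRUE` (needs >= 3 distinct fractions) both parameters are
#' estimated by linear regression of \eqn{\Delta C_T} on \eqn{\ln(f/(1-f))}.
#'
#' @param mixtures Data frame with columns `fraction` (known variant fraction,
#'   strictly inside (0,1)) and `delta_ct` (observed CT_var - CT_wt), one row
#'   per calibration measurement.
#' @param efficiency Fixed amplification efficiency; default 2 (perfect
#'   doubling, the near-ideal TaqMan case). Ignored when `fit_efficiency`.
#' @param fit_efficiency Jointly estimate `E` and `delta`.
#'
#' @return An object of class `calibration_model`: a list with `efficiency`,
#'   `delta`, `residual_sd`, `n`, `fitted_efficiency`.
#' @export
#' @examples
#' fit_calibration(data.frame(fraction = c(0.5, 1/3), delta_ct = c(0, 1)))
fit_calibration <- function(mixtures, efficiency = 2, fit_efficiency = FALSE) {
  mixtures <- as_tibble(mixtures)
  if (!all(c("fraction", "delta_ct") %in% names(mixtures))) {
    abort("`mixtures` needs columns `fraction` and `delta_ct`.")
  }
  f <- mixtures$fraction
  dct <- mixtures$delta_ct
  if (nrow(mixtures) < 2) abort("Need at least 2 calibration mixtures.")
  if (any(f <= 0 | f >= 1)) {
    abort("Calibration fractions must lie strictly inside (0, 1).")
  }
  if (length(unique(f)) < 2) {
    abort("Degenerate calibration design: all mixture fractions are equal.")
  }
  logit <- log(f / (1 - f))

  if (fit_efficiency) {
    if (length(unique(f)) < 3) {
      abort("Joint (efficiency, delta) fit needs >= 3 distinct fractions.")
    }
    fit <- lm(dct ~ logit)
    slope <- coef(fit)[["logit"]]
    if (slope >= 0) {
      abort("Calibration slope is non-negative; implied efficiency <= 1.")
    }
    efficiency <- exp(-1 / slope)
    delta <- coef(fit)[["(Intercept)"]]
    resid_sd <- if (nrow(mixtures) > 2) stats::sigma(fit) else 0
  } else {
    if (efficiency <= 1) abort("`efficiency` must exceed 1.")
    # with E fixed, the model is dct = delta - logit/ln(E): exact intercept
    resid0 <- dct + logit / log(efficiency)
    delta <- mean(resid0)
    resid_sd <- if (length(resid0) > 1) sd(resid0) else 0
  }

  structure(
    list(efficiency = unname(efficiency), delta = unname(delta),
         residual_sd = unname(resid_sd), n = nrow(mixtures),
         fitted_efficiency = fit_efficiency),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> E = %.4f%s, delta = %.4f cycles (residual SD %.4f, n = %d)\n",
    x$efficiency, if (x$fitted_efficiency) " (fitted)" else " (fixed)",
    x$delta, x$residual_sd, x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.calibration_model <- function(x, ...) {
  tibble(term = c("delta", "efficiency"),
         estimate = c(x$delta, x$efficiency),
         fitted = c(TRUE, x$fitted_efficiency))
}

#' @exportS3Method generics::glance
glance.calibration_model <- function(x, ...) {
  tibble(residual_sd = x$residual_sd, n = x$n,
         fitted_efficiency = x$fitted_efficiency)
}

#' Variant-clone fractions from qPCR CT measurements
#'
#' Inverts the calibration model: a measurement with CT difference
#' \eqn{\Delta C_T} maps to the variant fraction
#' \deqn{f = \frac{1}{1 + E^{\Delta C_T - \delta}}.}
#' The 95% interval transforms \eqn{\Delta C_T \pm 1.96\,s} through the same
#' map, where `s` is the calibration residual SD, so it respects the (0,1)
#' bounds by construction.
#'
#' @param measurements Data frame with columns `sample`, `replicate`, `ct_wt`,
#'   `ct_var` (a `tissue` column is carried through if present), or with a
#'   precomputed `delta_ct` column.
#' @param calibration A [fit_calibration()] model.
#'
#' @return A tibble with one row per measurement: identifying columns plus
#'   `delta_ct`, `fraction`, `conf.low`, `conf.high`, `source = "qpcr"`.
#' @export
quantify_qpcr <- function(measurements, calibration) {
  stopifnot(inherits(calibration, "calibration_model"))
  m <- as_tibble(measurements)
  if (!"delta_ct" %in% names(m)) {
    if (!all(c("ct_wt", "ct_var") %in% names(m))) {
      abort("`measurements` needs `ct_wt` and `ct_var` (or `delta_ct`).")
    }
    m$delta_ct <- m$ct_var - m$ct_wt
  }
  if (any(!is.finite(m$delta_ct))) {
    abort("Non-finite CT difference in measurements.")
  }
  E <- calibration$efficiency
  d <- calibration$delta
  s <- calibration$residual_sd
  inv <- function(dct) 1 / (1 + E^(dct - d))
  m$fraction <- inv(m$delta_ct)
  m$conf.low <- inv(m$delta_ct + 1.96 * s)   # larger dct -> smaller f
  m$conf.high <- inv(m$delta_ct - 1.96 * s)
  m$source <- "qpcr"
  id_cols <- intersect(c("sample", "tissue", "replicate"), names(m))
  dplyr::select(m, dplyr::all_of(id_cols), "delta_ct", "fraction",
                "conf.low", "conf.high", "source")
}

#' Variant fractions from allele-specific read counts
#'
#' Count-based analogue of [quantify_qpcr()] for cDNA sequencing readouts:
#' the point estimate is `alt / (alt + ref)` with a Wilson score 95% interval,
#' which stays inside \[0, 1\] at the boundaries.
#'
#' @param counts Data frame with columns `alt_reads` and `ref_reads` (an
#'   optional `sample` column is carried through).
#'
#' @return A tibble with `fraction`, `conf.low`, `conf.high`,
#'   `source = "counts"` per row.
#' @export
quantify_counts <- function(counts) {
  m <- as_tibble(counts)
  if (!all(c("alt_reads", "ref_reads") %in% names(m))) {
    abort("`counts` needs columns `alt_reads` and `ref_reads`.")
  }
  total <- m$alt_reads + m$ref_reads
  if (any(total < 1)) abort("Each row needs at least one read.")
  ci <- t(mapply(function(x, n) {
    # Wilson score interval = prop.test without continuity correction
    as.numeric(prop.test(x, n, correct = FALSE)$conf.int)
  }, m$alt_reads, total))
  m$fraction <- m$alt_reads / total
  m$conf.low <- ci[, 1]
  m$conf.high <- ci[, 2]
  m$source <- "counts"
  id_cols <- intersect(c("sample", "tissue"), names(m))
  dplyr::select(m, dplyr::all_of(id_cols), "alt_reads", "ref_reads",
                "fraction", "conf.low", "conf.high", "source")
}

#' One-sample t test of clone fractions against the XCI expectation
#'
#' Under random X inactivation with no selection, the expected variant-clone
#' fraction is 50%. This tests whether the mean of per-replicate (typically
#' per-animal) fractions departs from that expectation with a two-sided
#' one-sample t test.
#'
#' Degenerate zero-variance inputs are handled explicitly: all values equal
#' to the expectation give p = 1, all values equal but different from it give
#' p = 0, both flagged `degenerate = TRUE`.
#'
#' @param fractions Numeric vector of fractions (n >= 2), or a data frame
#'   holding them in a `fraction` column.
#' @param expected Null mean; default 0.5.
#'
#' @return An object of class `skew_test` (also a list): `n`, `mean`, `sd`,
#'   `statistic`, `df`, `p.value`, `expected`, `degenerate`.
#' @export
#' @examples
#' test_skew(c(0.40, 0.42, 0.44))  # t = -6.93, df = 2
test_skew <- function(fractions, expected = 0.5) {
  if (is.data.frame(fractions)) fractions <- fractions$fraction
  fractions <- as.numeric(fractions)
  if (length(fractions) < 2) {
    abort("Need at least 2 fraction values for the one-sample t test.")
  }
  n <- length(fractions)
  m <- mean(fractions)
  s <- sd(fractions)
  degenerate <- s == 0
  if (degenerate) {
    statistic <- if (m == expected) 0 else sign(m - expected) * Inf
    p <- if (m == expected) 1 else 0
  } else {
    statistic <- (m - expected) / (s / sqrt(n))
    p <- 2 * pt(-abs(statistic), df = n - 1)
  }
  structure(
    list(n = n, mean = m, sd = s, statistic = statistic, df = n - 1L,
         p.value = p, expected = expected, degenerate = degenerate),
    class = "skew_test"
  )
}

#' @export
print.skew_test <- function(x, ...) {
  cat(sprintf(
    "<skew_test> mean fraction %.4f vs expected %.2f: t = %.3f, df = %d, p = %.4g%s\n",
    x$mean, x$expected, x$statistic, x$df, x$p.value,
    if (x$degenerate) " (degenerate: zero variance)" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.skew_test <- function(x, ...) {
  tibble(estimate = x$mean, expected = x$expected, statistic = x$statistic,
         parameter = x$df, p.value = x$p.value, n = x$n, sd = x$sd,
         degenerate = x$degenerate,
         method = "one-sample t test vs XCI expectation")
}

#' @exportS3Method generics::glance
glance.skew_test <- function(x, ...) tidy(x)
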