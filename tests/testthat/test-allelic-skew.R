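test_that("calibration inverts exactly from two noiseless mixtures", {
  # (f = 0.5, dct = 0) and (f = 1/3, dct = 1) at E = 2 imply delta = 0
  cal <- fit_calibration(data.frame(fraction = c(0.5, 1 / 3),
                                    delta_ct = c(0, 1)), efficiency = 2)
  expect_equal(cal$delta, 0, tolerance = 1e-12)

  # noiseless simulated mixtures with delta = 1.5 recover delta exactly
  panel <- simulate_qpcr_panel(
    setNames(seq(0.1, 0.9, by = 0.1), paste0("mix", 1:9)),
    n_replicates = 1, delta = 1.5, noise_sd = 0, seed = 1)
  truth <- attr(panel, "truth")
  mix <- data.frame(fraction = truth$true_fraction,
                    delta_ct = panel$ct_var - panel$ct_wt)
  cal2 <- fit_calibration(mix, efficiency = 2)
  expect_equal(cal2$delta, 1.5, tolerance = 1e-9)

  # joint fit recovers a non-ideal efficiency from noiseless data
  panel3 <- simulate_qpcr_panel(
    setNames(c(0.2, 0.4, 0.6, 0.8), paste0("m", 1:4)),
    n_replicates = 1, efficiency = 1.9, delta = 0.7, noise_sd = 0, seed = 1)
  mix3 <- data.frame(fraction = attr(panel3, "truth")$true_fraction,
                     delta_ct = panel3$ct_var - panel3$ct_wt)
  cal3 <- fit_calibration(mix3, fit_efficiency = TRUE)
  expect_equal(cal3$efficiency, 1.9, tolerance = 1e-9)
  expect_equal(cal3$delta, 0.7, tolerance = 1e-9)
})

test_that("calibration rejects degenerate designs", {
  expect_error(fit_calibration(data.frame(fraction = 0.5, delta_ct = 0)),
               "at least 2")
  expect_error(fit_calibration(data.frame(fraction = c(0.5, 1),
                                          delta_ct = c(0, 3))),
               "strictly inside")
  expect_error(fit_calibration(data.frame(fraction = c(0.4, 0.4),
                                          delta_ct = c(0, 1))),
               "Degenerate")
  expect_error(fit_calibration(data.frame(fraction = c(0.3, 0.6),
                                          delta_ct = c(1, 0)),
                               fit_efficiency = TRUE),
               ">= 3 distinct")
})

test_that("qPCR quantification matches the closed-form inversion", {
  cal <- fit_calibration(data.frame(fraction = c(0.5, 1 / 3),
                                    delta_ct = c(0, 1)), efficiency = 2)
  q <- quantify_qpcr(data.frame(sample = "s", replicate = 1:3,
                                delta_ct = c(0, 1, -2)), cal)
  expect_equal(q$fraction, c(0.5, 1 / 3, 0.8))
  expect_error(quantify_qpcr(data.frame(delta_ct = NaN), cal), "finite")
})

test_that("qPCR fraction map is complement-symmetric and monotone", {
  cal <- structure(list(efficiency = 2, delta = 0, residual_sd = 0.1,
                        n = 8, fitted_efficiency = FALSE),
                   class = "calibration_model")
  dct <- seq(-4, 4, by = 0.25)
  f_pos <- quantify_qpcr(data.frame(delta_ct = dct), cal)$fraction
  f_neg <- quantify_qpcr(data.frame(delta_ct = -dct), cal)$fraction
  expect_equal(f_pos + f_neg, rep(1, length(dct)))
  expect_true(all(diff(f_pos) < 0))
  # interval contains the estimate and lies in [0, 1]
  q <- quantify_qpcr(data.frame(delta_ct = dct), cal)
  expect_true(all(q$conf.low <= q$fraction & q$fraction <= q$conf.high))
  expect_true(all(q$conf.low >= 0 & q$conf.high <= 1))
})

test_that("simulate -> calibrate -> quantify recovers true fractions", {
  # zero noise: recovery to numerical precision
  truth <- setNames(c(0.15, 0.4, 0.75), paste0("s", 1:3))
  panel <- simulate_qpcr_panel(truth, n_replicates = 2, delta = 0.8,
                               noise_sd = 0, seed = 3)
  calmix <- simulate_qpcr_panel(
    setNames(seq(0.2, 0.8, length.out = 4), paste0("c", 1:4)),
    n_replicates = 1, delta = 0.8, noise_sd = 0, seed = 4)
  cal <- fit_calibration(
    data.frame(fraction = attr(calmix, "truth")$true_fraction,
               delta_ct = calmix$ct_var - calmix$ct_wt))
  q <- quantify_qpcr(panel, cal)
  per_sample <- tapply(q$fraction, q$sample, mean)
  expect_equal(as.vector(per_sample[names(truth)]), unname(truth),
               tolerance = 1e-9)
})

test_that("count-based fractions use the Wilson interval", {
  q <- quantify_counts(data.frame(alt_reads = c(50, 3, 0),
                                  ref_reads = c(50, 97, 10)))
  expect_equal(q$fraction, c(0.5, 0.03, 0))
  # against the textbook closed form
  for (i in 1:3) {
    w <- wilson_interval(c(50, 3, 0)[i], c(100, 100, 10)[i])
    expect_equal(c(q$conf.low[i], q$conf.high[i]), w, tolerance = 1e-9)
  }
  expect_equal(q$conf.low[3], 0)
  expect_error(quantify_counts(data.frame(alt_reads = 0, ref_reads = 0)),
               "at least one read")
  # scale invariance of the point estimate
  q2 <- quantify_counts(data.frame(alt_reads = 3 * 7, ref_reads = 97 * 7))
  expect_equal(q2$fraction, 0.03)
})

test_that("skew t test matches hand computation and handles degeneracy", {
  r <- test_skew(c(0.40, 0.42, 0.44), expected = 0.5)
  # t = (0.42 - 0.5) / (0.02 / sqrt(3)) = -4 * sqrt(3)
  expect_equal(r$statistic, -4 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2L)
  # independent CDF route: for df = 2, P(T <= t) = 1/2 + t / (2 sqrt(2 + t^2))
  t_abs <- 4 * sqrt(3)
  p_closed <- 2 * (1 / 2 - t_abs / (2 * sqrt(2 + t_abs^2)))
  expect_equal(r$p.value, p_closed, tolerance = 1e-12)
  # agreement with stats::t.test as a second oracle
  tt <- t.test(c(0.40, 0.42, 0.44), mu = 0.5)
  expect_equal(r$p.value, tt$p.value, tolerance = 1e-12)

  expect_error(test_skew(0.4), "at least 2")
  deg_eq <- test_skew(c(0.5, 0.5, 0.5))
  expect_equal(deg_eq$p.value, 1)
  expect_true(deg_eq$degenerate)
  deg_ne <- test_skew(c(0.2, 0.2))
  expect_equal(deg_ne$p.value, 0)
  expect_true(deg_ne$degenerate)
})

test_that("tidy and glance methods return broom-shaped rows", {
  r <- tidy(test_skew(c(0.3, 0.35, 0.4)))
  expect_s3_class(r, "tbl_df")
  expect_true(all(c("estimate", "statistic", "parameter", "p.value")
                  %in% names(r)))
  cal <- fit_calibration(data.frame(fraction = c(0.3, 0.7),
                                    delta_ct = c(1, -1)))
  expect_equal(nrow(tidy(cal)), 2)
  expect_true("residual_sd" %in% names(glance(cal)))
})
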