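spectrum_with <- function(intensities) {
  lad <- HUMAN_1_16_LADDER
  mz <- lad$mz[match(names(intensities), lad$label)]
  new_spectrum(mz, unname(intensities), 1954.879)
}

test_that("marker_ratio arithmetic and error contract", {
  m <- match_fragments(spectrum_with(c(b6 = 50, b11 = 100)), HUMAN_1_16_LADDER)
  expect_equal(marker_ratio(m, "b6", "b11"), 0.5)

  no_base <- match_fragments(spectrum_with(c(b6 = 50)), HUMAN_1_16_LADDER)
  expect_error(marker_ratio(no_base, "b6", "b11"), "base fragment missing")

  no_marker <- match_fragments(spectrum_with(c(b11 = 100)), HUMAN_1_16_LADDER)
  expect_warning(r <- marker_ratio(no_marker, "b6", "b11"), "unmatched")
  expect_equal(r, 0)

  expect_error(marker_ratio(m, "b11", "b11"), "marker must be")
  expect_error(marker_ratio(m, "b6", "b7"), "base must be")
})

test_that("mean ratio is strictly increasing in iso fraction at zero noise", {
  cfg <- noise_free_config()
  ratios <- vapply(seq(0, 100, 10), function(f) {
    m <- match_fragments(simulate_spectrum(f, cfg), HUMAN_1_16_LADDER)
    marker_ratio(m)
  }, 0)
  expect_true(all(diff(ratios) > 0))
})

test_that("fit_calibration recovers an exact line and enforces its contract", {
  cv <- fit_calibration(c(0, 50, 100), c(0.2, 0.6, 1.0))
  expect_equal(cv$slope, 0.008)
  expect_equal(cv$intercept, 0.2)
  expect_equal(cv$fit_kind, "linear")

  expect_error(fit_calibration(c(0, 100), c(0.2, 1.0)), "3 distinct")
  expect_error(fit_calibration(c(0, 10, 20), c(0.2, 0.3, 0.4)),
               "50 percentage points")
  expect_error(fit_calibration(c(0, 50, 100), c(0.5, 0.5, 0.5)),
               "non-monotone")
  expect_error(fit_calibration(c(0, 50, 100), c(1.0, 0.6, 0.2)),
               "non-monotone")
})

test_that("fitted line recovers the generator slope within 2 SE", {
  set.seed(7)
  series <- simulate_calibration_series(10, 3, spectrum_sim_config(noise_cv = 0.05))
  cv <- calibrate_from_series(series)
  # generator truth: b6 40 -> 80, b11 fixed at 100 => slope 0.004, intercept 0.4
  expect_lt(abs(cv$slope - 0.004), 2 * cv$slope_se)
  expect_lt(abs(cv$intercept - 0.4), 2 * cv$intercept_se)
})

test_that("predict_fraction inverts the curve and clamps to [0, 100]", {
  cv <- fit_calibration(c(0, 50, 100), c(0.2, 0.6, 1.0))
  expect_equal(predict_fraction(cv, 0.6)$fraction_pct, 50)
  low <- predict_fraction(cv, 0.1)
  expect_equal(low$fraction_pct, 0)
  expect_true(low$clamped)
  high <- predict_fraction(cv, 1.5)
  expect_equal(high$fraction_pct, 100)
  expect_true(high$clamped)
  expect_false(predict_fraction(cv, 0.6)$clamped)
})

test_that("noise-free design round-trips through fit + inverse prediction", {
  cfg <- noise_free_config()
  series <- simulate_calibration_series(10, 1, cfg)
  cv <- calibrate_from_series(series)
  for (f in seq(0, 100, 10)) {
    m <- match_fragments(simulate_spectrum(f, cfg), HUMAN_1_16_LADDER)
    est <- predict_fraction(cv, marker_ratio(m))
    expect_lt(abs(est$fraction_pct - f), 1)
  }
})

test_that("estimate_sample: point cases and stochastic recovery", {
  cfg0 <- noise_free_config()
  curve <- calibrate_from_series(simulate_calibration_series(10, 1, cfg0))

  # single noise-free spectrum at f = 0
  est0 <- estimate_sample(list(simulate_spectrum(0, cfg0)), curve)
  expect_equal(est0$fraction_pct, 0, tolerance = 1e-6)
  expect_equal(est0$n_spectra, 1)

  # duplicated spectra give the identical estimate with sd 0
  s <- simulate_spectrum(40, spectrum_sim_config(), seed = 2)
  dup <- estimate_sample(list(s, s, s), curve)
  single <- estimate_sample(list(s), curve)
  expect_equal(dup$fraction_pct, single$fraction_pct)
  expect_equal(dup$ratio_sd, 0)
  expect_equal(dup$sd_pct, 0)

  # noisy recovery at f = 30: a single 20-spectrum estimate has an SE of
  # ~4 pct points under this noise model, so the 5-point tolerance is
  # checked on the mean absolute error of repeated estimates
  set.seed(11)
  cfg <- spectrum_sim_config(noise_cv = 0.10)
  errs <- replicate(10, {
    spectra <- lapply(1:20, function(r) simulate_spectrum(30, cfg, replicate = r))
    est <- estimate_sample(spectra, curve)
    expect_equal(est$n_spectra, 20)
    abs(est$fraction_pct - 30)
  })
  expect_lt(mean(errs), 5)
})

test_that("estimate_sample averaging modes and failure contract", {
  cfg0 <- noise_free_config()
  curve <- calibrate_from_series(simulate_calibration_series(10, 1, cfg0))
  spectra <- lapply(1:5, function(r) simulate_spectrum(60, cfg0, replicate = r))
  mr <- estimate_sample(spectra, curve, average = "ratios")
  ma <- estimate_sample(spectra, curve, average = "accumulated")
  expect_equal(mr$fraction_pct, ma$fraction_pct, tolerance = 0.5)

  # spectra lacking the base fragment everywhere
  bare <- list(new_spectrum(500, 10, 1954.879))
  expect_error(suppressWarnings(estimate_sample(bare, curve)),
               "base fragment missing")
})

test_that("estimate SD shrinks with more replicate spectra", {
  cfg <- spectrum_sim_config(noise_cv = 0.10)
  curve <- calibrate_from_series(simulate_calibration_series(10, 1, noise_free_config()))
  set.seed(21)
  err5 <- replicate(40, {
    est <- estimate_sample(lapply(1:5, function(r) simulate_spectrum(30, cfg)), curve)
    est$fraction_pct - 30
  })
  err20 <- replicate(40, {
    est <- estimate_sample(lapply(1:20, function(r) simulate_spectrum(30, cfg)), curve)
    est$fraction_pct - 30
  })
  expect_lt(sd(err20), sd(err5))
})

test_that("marker channels b6/b11 and y10/y11 give consistent estimates", {
  cfg <- spectrum_sim_config(noise_cv = 0.05)
  cfg0 <- noise_free_config()
  cv_b <- calibrate_from_series(simulate_calibration_series(10, 1, cfg0),
                                marker = "b6", base = "b11")
  cv_y <- calibrate_from_series(simulate_calibration_series(10, 1, cfg0),
                                marker = "y10", base = "y11")
  set.seed(31)
  spectra <- lapply(1:20, function(r) simulate_spectrum(45, cfg))
  eb <- estimate_sample(spectra, cv_b, marker = "b6", base = "b11")
  ey <- estimate_sample(spectra, cv_y, marker = "y10", base = "y11")
  expect_lt(abs(eb$fraction_pct - ey$fraction_pct),
            3 * (eb$sd_pct + ey$sd_pct) + 1)
})

test_that("matrix_effect_check verdicts", {
  set.seed(41)
  cfg <- spectrum_sim_config(noise_cv = 0.05)
  c1 <- calibrate_from_series(simulate_calibration_series(10, 5, cfg))
  # identical curve objects: all differences zero, p = 1
  same <- matrix_effect_check(list(c1, c1))
  expect_equal(same$verdict, "comparable")
  expect_true(all(same$comparisons[, c("p_slope", "p_intercept")] == 1))

  # doubled generator slope (marker enhancement 3 instead of 2) is flagged
  cfg_dbl <- spectrum_sim_config(noise_cv = 0.05, marker_enhancement = 3)
  c2 <- calibrate_from_series(simulate_calibration_series(10, 5, cfg_dbl))
  expect_equal(matrix_effect_check(list(c1, c2))$verdict, "different")

  expect_error(matrix_effect_check(list(c1)), "at least two")
  c3 <- fit_calibration(c(0, 25, 50, 75, 100), c(0.2, 0.4, 0.6, 0.8, 1.0))
  expect_error(matrix_effect_check(list(c1, c3)), "mismatched")
})

test_that("matrix_effect_check type-I: same-generator curves look comparable", {
  set.seed(51)
  cfg <- spectrum_sim_config(noise_cv = 0.05)
  n_comparable <- sum(replicate(100, {
    a <- calibrate_from_series(simulate_calibration_series(10, 3, cfg))
    b <- calibrate_from_series(simulate_calibration_series(10, 3, cfg))
    matrix_effect_check(list(a, b))$verdict == "comparable"
  }))
  expect_gte(n_comparable, 90)
})
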