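# roex(p) filter model, power-spectrum-model predictions, fitting.

test_that("roex weight matches the closed form and is monotone", {
  expect_equal(roex_weight(0, 7), 1)
  expect_equal(roex_weight(0, 93), 1)
  expect_equal(roex_weight(0.1, 20), 3 * exp(-2))
  g <- seq(0, 1, by = 0.01)
  for (p in c(5, 20, 80)) {
    w <- roex_weight(g, p)
    expect_true(all(diff(w) < 0))
    expect_true(all(w > 0 & w <= 1))
  }
  expect_error(roex_weight(-0.1, 20), "non-negative")
})

test_that("closed-form band integral agrees with adaptive quadrature", {
  for (p in c(5, 11.3, 36.04, 100)) {
    for (lims in list(c(0, 0.0425), c(0.01, 0.3), c(0.2, 1))) {
      closed <- roex_band_integral(p, lims[1], lims[2])
      quad <- integrate(function(g) roex_weight(g, p), lims[1], lims[2],
        rel.tol = 1e-12
      )$value
      expect_equal(closed, quad, tolerance = 1e-8)
    }
    # half the total area from one skirt
    expect_equal(roex_band_integral(p, 0, Inf), 2 / p)
    expect_equal(roex_band_integral(p, 0.3, 0.3), 0)
  }
  expect_error(roex_band_integral(20, 0.5, 0.2), "g1 <= g2")
})

test_that("ERB identity: integrated filter width equals 4 fc / p", {
  for (p in c(10, 35.09, 70)) {
    filt <- roex_filter(4000, p = p)
    # both skirts: 2 * fc * integral of W from 0 to Inf
    erb_num <- 2 * 4000 *
      integrate(function(g) roex_weight(g, p), 0, Inf, rel.tol = 1e-10)$value
    expect_equal(erb_num, filt$erb_hz, tolerance = 1e-3)
  }
  # fraction of total area within +/- ERB/2 of fc: 1 - 2 e^-2
  p <- 25
  frac <- 2 * roex_band_integral(p, 0, 2 / p) / (4 / p)
  expect_equal(frac, 1 - 2 * exp(-2), tolerance = 1e-12)
})

test_that("Glasberg-Moore ERB reproduces the published values", {
  expect_equal(signif(glasberg_moore_erb(4000), 3), 456)
  expect_equal(signif(glasberg_moore_erb(8000), 3), 888)
  expect_equal(glasberg_moore_erb(1000), 132.639, tolerance = 1e-3)
  expect_equal(round(erb_power_ratio(1087, 888), 1), 0.9)
  expect_equal(erb_power_ratio(555, 555), 0)
  expect_equal(erb_power_ratio(1000, 500), 10 * log10(2))
})

test_that("predicted notch thresholds fall with notch width, shift with density", {
  filt <- roex_filter(4000, erb_hz = 456)
  th <- vapply(c(0, 0.1, 0.2, 0.3), function(d) {
    predict_notch_threshold(
      filt, cortone:::notch_masker_bands(4000, d, 67.9), efficiency_k_db = 0
    )
  }, numeric(1))
  expect_true(all(diff(th) < 0))
  # +3 dB masker level -> +3 dB threshold exactly (linearity in power)
  th3 <- predict_notch_threshold(
    filt, cortone:::notch_masker_bands(4000, 0.1, 70.9), efficiency_k_db = 0
  )
  expect_equal(th3, th[2] + 3, tolerance = 1e-9)
  # absolute-threshold floor clips from below
  expect_equal(
    predict_notch_threshold(
      filt, cortone:::notch_masker_bands(4000, 0.3, 67.9), 0, floor_db = 60
    ),
    60
  )
})

test_that("SMR at the filter output tracks the probe level", {
  filt <- roex_filter(8000, erb_hz = 1087)
  bands <- cortone:::notch_masker_bands(8000, 0, 73)
  s1 <- smr_at_filter_output(75, bands, filt)
  s2 <- smr_at_filter_output(80, bands, filt)
  expect_equal(s2 - s1, 5)
})

test_that("fit_roex inverts noiseless synthetic thresholds", {
  d <- sim_notch_thresholds(
    true_erb_hz = 456, fc_hz = 4000, efficiency_k_db = -2,
    noise_sd_db = 0, n_subjects = 1, masker_level_db_spl = 67.9, seed = 1
  )
  fit <- fit_roex(d, 4000, 67.9)
  expect_equal(fit$p_hat, 4 * 4000 / 456, tolerance = 0.005)
  expect_equal(fit$erb_hat_hz, 456, tolerance = 456 * 0.005)
  expect_equal(fit$efficiency_k_db, -2, tolerance = 0.01)
  expect_true(fit$converged)
  expect_equal(nrow(tidy(fit)), 4)
  expect_equal(glance(fit)$erb_hz, fit$erb_hat_hz)

  two <- d[d$delta_f_frac < 0.15, ]
  expect_error(fit_roex(two, 4000, 67.9), ">= 3 notch widths")
})

test_that("fit_roex recovers a cat-like ERB from noisy cohorts", {
  errs <- vapply(1:40, function(i) {
    d <- sim_notch_thresholds(1087, 8000, -2, noise_sd_db = 1, n_subjects = 4,
                              masker_level_db_spl = 73, seed = 100 + i)
    abs(fit_roex(d, 8000, 73)$erb_hat_hz - 1087) / 1087
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("bootstrap ERB is deterministic and degenerate for identical subjects", {
  d <- sim_notch_thresholds(477, 4000, -2, noise_sd_db = 0, n_subjects = 5,
                            masker_level_db_spl = 67.9, seed = 2)
  b1 <- bootstrap_erb(d, 4000, 67.9, n_boot = 50, seed = 9)
  b2 <- bootstrap_erb(d, 4000, 67.9, n_boot = 50, seed = 9)
  expect_identical(b1$erb_hz, b2$erb_hz)
  # identical subjects (no noise): every resample refits the same data
  expect_equal(b1$erb_boot_sd_hz, 0, tolerance = 1e-6)
  expect_equal(b1$erb_boot_mean_hz, 477, tolerance = 1)

  noisy <- sim_notch_thresholds(477, 4000, -2, noise_sd_db = 2, n_subjects = 11,
                                masker_level_db_spl = 67.9, seed = 3)
  fit <- fit_roex(noisy, 4000, 67.9)
  b <- bootstrap_erb(noisy, 4000, 67.9, n_boot = 200, seed = 4)
  expect_gt(b$erb_boot_sd_hz, 0)
  # bootstrap mean within 3 SD of the point estimate
  expect_lt(abs(b$erb_boot_mean_hz - fit$erb_hat_hz), 3 * b$erb_boot_sd_hz)
  expect_error(
    bootstrap_erb(noisy[noisy$subject == "S1", ], 4000, 67.9, 10, 1),
    ">= 2 subjects"
  )
})
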