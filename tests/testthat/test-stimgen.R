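# Stimulus synthesis: band geometry, calibration, spectral containment.

test_that("band_edges gives geometric cutoffs and matches printed passbands", {
  e <- band_edges(4000, 1 / 8)
  expect_equal(unname(e), c(4000 * 2^(-1 / 16), 4000 * 2^(1 / 16)))
  expect_equal(sqrt(prod(e)), 4000, tolerance = 1e-4)
  # zero-width band collapses onto the centre
  expect_equal(unname(band_edges(1234, 0)), c(1234, 1234))
  expect_error(band_edges(-1, 1), "positive")
  expect_error(band_edges(1000, -0.5), "non-negative")
})

test_that("band noise is calibrated, brick-walled and seed-deterministic", {
  spec <- band_spec(8000, 1 / 8, 65)
  x <- make_band_noise(spec, 1, 32000, seed = 1)
  # level calibration within 0.1 dB
  expect_equal(signal_level_db(x), 65, tolerance = 0.1)
  # spectral containment: out-of-band at least 60 dB below in-band
  inband <- band_level_db(x, spec$f_lo_hz, spec$f_hi_hz)
  out <- band_level_db(x, 100, spec$f_lo_hz - 200) +
    band_level_db(x, spec$f_hi_hz + 200, 15000)
  expect_lt(band_level_db(x, 100, spec$f_lo_hz - 200), inband - 60)
  expect_lt(band_level_db(x, spec$f_hi_hz + 200, 15000), inband - 60)
  # determinism and seed sensitivity
  expect_identical(x$samples, make_band_noise(spec, 1, 32000, seed = 1)$samples)
  y <- make_band_noise(spec, 1, 32000, seed = 2)
  expect_false(identical(x$samples, y$samples))
  # same magnitude spectrum for different seeds (flat construction)
  expect_equal(abs(fft(x$samples)), abs(fft(y$samples)), tolerance = 1e-6)
  # 6-dB level step reproduced in the waveform RMS
  a <- make_band_noise(band_spec(8000, 1 / 8, 60), 1, 32000, seed = 3)
  b <- make_band_noise(band_spec(8000, 1 / 8, 66), 1, 32000, seed = 4)
  expect_equal(signal_level_db(b) - signal_level_db(a), 6, tolerance = 0.05)
  expect_error(make_band_noise(spec, 1, 16000, seed = 1), "Nyquist|twice")
})

test_that("pink noise has equal energy per octave at the stated slice level", {
  x <- make_pink_noise(85, 3700, 30, 2, 16000, seed = 5)
  # octave [100,200] vs octave [1000,2000] within 0.5 dB
  expect_equal(band_level_db(x, 100, 200), band_level_db(x, 1000, 2000),
    tolerance = 0.5
  )
  # any 1/6-oct slice carries the requested level
  expect_equal(band_level_db(x, 1000, 1000 * 2^(1 / 6)), 30, tolerance = 0.5)
  expect_equal(band_level_db(x, 400, 400 * 2^(1 / 6)), 30, tolerance = 0.5)
  # human preset upper edge synthesizes fine
  y <- make_pink_noise(85, 1860, 30, 1, 16000, seed = 6)
  expect_s3_class(y, "sampled_signal")
  expect_error(make_pink_noise(1000, 1000, 30, 1, 16000, 1), "exceed")
})

test_that("notched noise keeps flanking widths constant and a silent notch", {
  spec <- notch_spec(4000, 0.3, 67.9)
  # notch edges at centre*(1 -/+ delta)
  expect_equal(spec$bands$f_hi_hz[1], 2800)
  expect_equal(spec$bands$f_lo_hz[2], 5200)
  # widths equal those at delta = 0.1 (constant-width rule)
  s01 <- notch_spec(4000, 0.1, 67.9)
  expect_equal(
    spec$bands$f_hi_hz - spec$bands$f_lo_hz,
    s01$bands$f_hi_hz - s01$bands$f_lo_hz
  )
  # delta = 0 reproduces the 1-oct band edges exactly
  s0 <- notch_spec(4000, 0, 67.9)
  e <- band_edges(4000, 1)
  expect_equal(s0$bands$f_lo_hz[1], unname(e["f_lo_hz"]))
  expect_equal(s0$bands$f_hi_hz[2], unname(e["f_hi_hz"]))

  x <- make_notched_noise(spec, 1, 32000, seed = 7)
  expect_equal(signal_level_db(x), 67.9, tolerance = 0.1)
  # spectral density inside the notch at least 60 dB below passband density
  dens_pass <- band_level_db(x, 2400, 2800) - 10 * log10(400)
  dens_notch <- band_level_db(x, 3000, 5000) - 10 * log10(2000)
  expect_lt(dens_notch, dens_pass - 60)
  expect_error(notch_spec(4000, 0.6, 60), "0.5")
})

test_that("notched noise at zero width matches the 1-oct band density", {
  s0 <- make_notched_noise(notch_spec(4000, 0, 65), 1, 32000, seed = 8)
  b1 <- make_band_noise(band_spec(4000, 1, 65), 1, 32000, seed = 9)
  d0 <- band_level_db(s0, 3000, 5000)
  d1 <- band_level_db(b1, 3000, 5000)
  expect_equal(d0, d1, tolerance = 0.2)
})

test_that("tone probes are calibrated with the species ramp presets", {
  tp <- make_tone_probe(probe_spec(8000, 75, species = "cat"), 32000)
  expect_equal(tp$meta$spec$ramp_ms, 5)
  expect_equal(tp$meta$spec$ramp_shape, "cosine-squared")
  n <- length(tp$samples)
  steady <- tp$samples[(n %/% 4):(3 * n %/% 4)]
  expect_equal(20 * log10(sqrt(mean(steady^2)) / 20e-6), 75, tolerance = 0.1)

  hp <- probe_spec(4000, 70, species = "human")
  expect_equal(hp$ramp_ms, 2)
  expect_equal(hp$ramp_shape, "sine-squared")

  # zero ramp = rectangular gate: first sample already at full amplitude
  rect <- make_tone_probe(
    probe_spec(1000, 70, ramp_ms = 0, species = "cat"), 32000,
    phase = pi / 2
  )
  expect_equal(rect$samples[1], sqrt(2) * 20e-6 * 10^(70 / 20))
  expect_error(probe_spec(1000, 70, duration_ms = 8, ramp_ms = 5), "twice")
})

test_that("masker equalization passes equal power through a rectangular ERB", {
  # printed case: 1/8- vs 1-oct at 4 kHz, 456-Hz ERB -> +7.9 dB
  off4 <- equalize_masker_level(
    band_spec(4000, 1 / 8, 60), band_spec(4000, 1, 60), 456
  )
  expect_equal(round(off4, 1), 7.9)
  # derived case at 8 kHz: narrow passes fully -> 10log10(BW_wide/888)
  off8 <- equalize_masker_level(
    band_spec(8000, 1 / 8, 65), band_spec(8000, 1, 65), 888
  )
  expect_equal(off8, 10 * log10(8000 * (2^0.5 - 2^-0.5) / 888),
    tolerance = 1e-10
  )
  expect_equal(round(off8, 1), 8)
  # both bands wider than the ERB: density-equalization limit
  lim <- equalize_masker_level(
    band_spec(4000, 1 / 2, 60), band_spec(4000, 1, 60), 100
  )
  bw_n <- 4000 * (2^0.25 - 2^-0.25)
  bw_w <- 4000 * (2^0.5 - 2^-0.5)
  expect_equal(lim, 10 * log10(bw_w / bw_n), tolerance = 1e-10)
  expect_error(
    equalize_masker_level(band_spec(4000, 1, 60), band_spec(8000, 1, 60), 456),
    "centre"
  )
})
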