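# COR extraction: montage, epoching, filtering, rejection, peaks.

test_that("montage derivation is stimulation-side aware and exact", {
  n <- 1000
  sig <- sin(seq_len(n) / 20)
  data <- rbind(
    P7 = sig, P8 = numeric(n), Cz = numeric(n),
    EyeAbove = numeric(n), EyeBelow = numeric(n)
  )
  rec <- list(data = data, rate_hz = 500, stim_ear = "right")
  # dipole injected at the mastoid only is recovered unchanged
  expect_equal(derive_channel(rec, "auto"), sig)
  rec$stim_ear <- "left"
  expect_equal(derive_channel(rec, "auto"), numeric(n)) # P8 - Cz, both zero
  # identical channels difference to a zero trace
  expect_equal(derive_channel(rec, c("Cz", "Cz")), numeric(n))
  expect_error(derive_channel(rec, c("Oz", "Cz")), "not in recording")
})

test_that("epoching honours the sweep structure and first-probe drop", {
  rate <- 500
  trg <- do.call(rbind, lapply(1:20, function(s) {
    data.frame(
      time_s = (s - 1) * 15 + 2 + 0:12, sweep = s, probe_idx = 1:13
    )
  }))
  trace <- rnorm(round(rate * 310))
  ep <- epoch_trace(trace, trg, rate, c(-200, 600), drop_first_per_sweep = TRUE)
  expect_equal(nrow(ep$data), 240) # 12 probes x 20 blocks
  ep_all <- epoch_trace(trace, trg, rate, c(-200, 600))
  expect_equal(nrow(ep_all$data), 260)
  # window indexing: onset sample is time 0, values map back to the trace
  one <- epoch_trace(seq_along(trace), trg[5, , drop = FALSE], rate, c(-10, 10))
  i0 <- round(trg$time_s[5] * rate) + 1
  expect_equal(one$data[1, one$times_ms == 0], i0)
  expect_error(
    epoch_trace(trace, data.frame(time_s = 0.05), rate, c(-200, 600)),
    "beyond the recording"
  )
})

test_that("the FIR bandpass passes the band and rejects out-of-band energy", {
  cfg <- human_cfg()
  rate <- 500
  t <- seq(0, 0.8 - 1 / rate, by = 1 / rate)
  mk_ep <- function(x) {
    structure(
      list(
        data = matrix(x, nrow = 1), times_ms = t * 1000 - 200, rate_hz = rate,
        info = tibble::tibble(time_s = 1, rejected = FALSE,
                              reject_reason = NA_character_)
      ),
      class = "cor_epochs"
    )
  }
  amp_of <- function(x) (max(x) - min(x)) / 2
  # 10 Hz passes within 1 dB
  f10 <- bandpass_epochs(mk_ep(sin(2 * pi * 10 * t)), cfg)
  expect_gt(20 * log10(amp_of(f10$data[1, ])), -1)

  # frequency-response oracle: >= 40 dB attenuation one transition width
  # beyond the band edges, and at 50 Hz and DC
  b <- cortone:::fir_design(rate, cfg$filter_band_hz, cfg$transition_hz)
  H <- function(f) {
    abs(sum(b * exp(-1i * 2 * pi * f * (seq_along(b) - 1) / rate)))
  }
  expect_lt(20 * log10(H(50)), -40)
  expect_lt(20 * log10(H(0)), -40)
  expect_lt(20 * log10(H(cfg$filter_band_hz[2] + cfg$transition_hz)), -40)
  expect_gt(20 * log10(H(10)), -1)

  # a 50-Hz burst confined to the epoch core is removed in place
  burst <- sin(2 * pi * 50 * t) * exp(-(t - 0.4)^2 / (2 * 0.05^2))
  fb <- bandpass_epochs(mk_ep(burst), cfg)
  core <- t > 0.3 & t < 0.5
  expect_lt(20 * log10(amp_of(fb$data[1, core])), -30)
  # DC offset removed by the 1-20 Hz preset
  fdc <- bandpass_epochs(mk_ep(rep(3, length(t))), cfg)
  expect_lt(max(abs(fdc$data[1, ])) / 3, 10^(-30 / 20))
})

test_that("artifact flagging is pure and matches the species rules", {
  set.seed(11)
  ep <- toy_epochs(rep(1, 50), noise_sd = 0.5)
  cfg <- cat_cfg()
  clean <- reject_artifacts(ep, cfg)
  expect_equal(sum(clean$info$rejected), 0)
  # a 5x RMS spike inside 0-120 ms flags exactly that epoch
  idx <- which(ep$times_ms >= 0 & ep$times_ms <= 120)
  bg <- sqrt(mean(ep$data[, idx]^2))
  ep$data[7, idx[10]] <- 5.5 * bg
  flagged <- reject_artifacts(ep, cfg)
  expect_true(flagged$info$rejected[7])
  expect_equal(sum(flagged$info$rejected), 1)
  # flagging never alters the samples
  expect_identical(flagged$data, ep$data)

  # human rule: epochs crossing |z| > 4 on the eye trace are flagged
  set.seed(12)
  ep2 <- toy_epochs(rep(1, 40), noise_sd = 0.2)
  eye <- ep2
  eye$data <- matrix(0.5 * rnorm(length(ep2$data)), nrow = nrow(ep2$data))
  eye$data[c(3, 9), 50] <- 6
  hum <- reject_artifacts(ep2, human_cfg(), eye_epochs = eye)
  expect_equal(which(hum$info$rejected), c(3, 9))
})

test_that("averaging excludes flagged epochs, corrects baseline, shrinks noise", {
  ep <- toy_epochs(rep(2, 8))
  cfg <- human_cfg()
  avg <- average_epochs(ep, cfg)
  expect_equal(avg$n_epochs_used, 8)
  # identical epochs: mean equals any single epoch
  expect_equal(avg$waveform, ep$data[1, ], tolerance = 1e-10)
  # a constant offset is removed by the pre-onset baseline
  ep_off <- ep
  ep_off$data <- ep_off$data + 3
  expect_equal(average_epochs(ep_off, cfg)$waveform, avg$waveform,
    tolerance = 1e-10
  )
  # flagged epochs are excluded
  ep2 <- ep
  ep2$data[1, ] <- 1e6
  ep2$info$rejected[1] <- TRUE
  expect_equal(average_epochs(ep2, cfg)$n_epochs_used, 7)
  expect_equal(average_epochs(ep2, cfg)$waveform, avg$waveform,
    tolerance = 1e-10
  )
  ep3 <- ep
  ep3$info$rejected <- TRUE
  expect_error(average_epochs(ep3, cfg), "all epochs rejected")

  # residual noise shrinks roughly as 1/sqrt(N)
  set.seed(13)
  resid_rms <- function(n) {
    e <- toy_epochs(rep(1, n), noise_sd = 1)
    a <- average_epochs(e, cat_cfg())
    t <- toy_epochs(1)$data[1, ]
    sqrt(mean((a$waveform - t)^2))
  }
  r10 <- mean(replicate(5, resid_rms(10)))
  r160 <- mean(replicate(5, resid_rms(160)))
  expect_equal(r10 / r160, 4, tolerance = 1.5)
})

test_that("peak picking follows the species rules", {
  # human: global extrema in their windows; amplitude = P2 - N1 = 7 uV
  avg <- average_epochs(toy_epochs(1), human_cfg())
  res <- pick_peaks(avg)
  expect_equal(cor_amplitude(res), 7, tolerance = 0.05)
  expect_equal(res$latency_ms[res$peak == "N1"], 100, tolerance = 4)
  expect_equal(res$latency_ms[res$peak == "P2"], 180, tolerance = 4)

  # flat waveform: peaks absent under the cat slope-reversal rule
  flat <- avg
  flat$waveform <- rep(0, length(flat$waveform))
  flat$config <- cat_cfg(epoch_window_ms = c(-200, 600))
  res_flat <- pick_peaks(flat, flat$config)
  expect_false(any(res_flat$found))
  expect_true(is.na(cor_amplitude(res_flat)))

  # cat: earliest slope reversal of the right polarity in each window
  rate <- 500
  times <- seq(-50, 250, by = 1000 / rate)
  wf <- 2 * exp(-(times - 30)^2 / (2 * 8^2)) - 3 * exp(-(times - 80)^2 / (2 * 12^2))
  cavg <- structure(
    list(waveform = wf, times_ms = times, rate_hz = rate, n_epochs_used = 1,
         config = cat_cfg()),
    class = "cor_average"
  )
  cres <- pick_peaks(cavg)
  expect_equal(cres$latency_ms[cres$peak == "P1"], 30, tolerance = 4)
  expect_equal(cres$latency_ms[cres$peak == "N1"], 80, tolerance = 4)
  expect_equal(cor_amplitude(cres), 5, tolerance = 0.15)
})

test_that("peak latencies stay accurate at realistic noise", {
  set.seed(14)
  hits <- replicate(100, {
    ep <- toy_epochs(rep(1, 60), noise_sd = 2)
    res <- pick_peaks(average_epochs(ep, human_cfg()))
    all(abs(res$latency_ms - c(100, 180)) < 10)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("dB re unmasked follows a 20 log10 rule", {
  expect_equal(to_db_re_unmasked(5, 5), 0)
  expect_equal(to_db_re_unmasked(2.5, 5), 20 * log10(0.5))
  expect_error(to_db_re_unmasked(-1, 5), "positive")
  expect_error(to_db_re_unmasked(3, 0), "positive")
})

test_that("pipeline output is invariant to epoch order", {
  conds <- tibble::tibble(condition = "A", cor_masking_db = 0)
  s <- sim_eeg_session(conds, species = "human", n_blocks = 4, seed = 31)
  cfg <- human_cfg()
  r1 <- cor_pipeline(s$recording, s$triggers, cfg)
  perm <- withr::with_seed(1, sample(nrow(s$triggers)))
  r2 <- cor_pipeline(s$recording, s$triggers[perm, ], cfg)
  expect_equal(r1$amplitude_uv, r2$amplitude_uv, tolerance = 1e-10)
})
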