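# --- synthetic EEG with known COR amplitudes ------------------------------

#' 1/f scalp-noise generator
#'
#' Frequency-domain synthesis of EEG-like background noise with amplitude
#' proportional to `1/sqrt(f)` down to `f_floor_hz` (flat below), scaled to
#' a target RMS. Deterministic given the seed.
#'
#' @param n_samples Number of samples.
#' @param rate_hz Sampling rate (Hz).
#' @param rms_uv Target RMS (uV).
#' @param f_floor_hz Frequency below which the spectrum flattens.
#' @param seed Integer seed.
#' @return Numeric vector (uV).
#' @export
one_over_f_noise <- function(n_samples, rate_hz, rms_uv = 8,
                             f_floor_hz = 0.5, seed = 1) {
  n <- 2 * ceiling(n_samples / 2)
  freqs <- (1:(n / 2 - 1)) * rate_hz / n
  amp <- 1 / sqrt(pmax(freqs, f_floor_hz))
  phases <- withr::with_seed(seed, runif(length(freqs), -pi, pi))
  pos <- amp * exp(1i * phases)
  full <- c(0, pos, 0, Conj(rev(pos)))
  x <- Re(fft(full, inverse = TRUE)) / n
  x <- x[seq_len(n_samples)]
  x * rms_uv / rms(x)
}

# Sum-of-Gaussians template; widths are FWHM in ms.
template_waveform <- function(times_ms, peaks) {
  wf <- numeric(length(times_ms))
  for (i in seq_len(nrow(peaks))) {
    sigma <- peaks$width_ms[i] / 2.355
    wf <- wf + peaks$amplitude_uv[i] *
      exp(-(times_ms - peaks$latency_ms[i])^2 / (2 * sigma^2))
  }
  wf
}

#' Default COR waveform templates
#'
#' Peak parameters of the synthetic onset-response templates. The human
#' template has N1 (-4 uV at 100 ms) and P2 (+3 uV at 180 ms); the cat
#' template has P1 (+2 uV at 30 ms) and N1 (-3 uV at 80 ms). Latencies sit
#' inside the species' peak-picking windows.
#'
#' @param species `"human"` or `"cat"`.
#' @return Tibble with `peak`, `latency_ms`, `amplitude_uv`, `width_ms`.
#' @export
eeg_template <- function(species = c("human", "cat")) {
  species <- match.arg(species)
  if (species == "human") {
    tibble(
      peak = c("N1", "P2"),
      latency_ms = c(100, 180),
      amplitude_uv = c(-4, 3),
      width_ms = c(55, 70)
    )
  } else {
    tibble(
      peak = c("P1", "N1"),
      latency_ms = c(30, 80),
      amplitude_uv = c(2, -3),
      width_ms = c(25, 45)
    )
  }
}

#' Simulate a triggered scalp recording with known COR amplitudes
#'
#' Generates a continuous multichannel recording laid out like the
#' reference sessions: for each condition, `n_blocks` sweeps of
#' `probes_per_sweep` probes at a 1-s onset asynchrony, sweeps from all
#' conditions interleaved with a 1.2-s gap. The first probe of each sweep
#' coincides with the masker onset, so the analysis pipeline drops it
#' (leaving, with the defaults, 12 x 20 = 240 analysable epochs per
#' condition).
#'
#' Each condition's true response amplitude scales the species template by
#' `10^((slope * (probe_level - ref_level) + cor_masking_db) / 20)`: a
#' level-growth law on top of a per-condition masking law (supply
#' `cor_masking_db` directly in `conditions`, or derive it from
#' [predicted_masking()] times the growth slope). Background noise is 1/f
#' with RMS `noise_rms_uv` per channel; ocular artifacts (large slow
#' deflections, strongest on the eye channels) are injected in a random
#' fraction `artifact_rate` of epochs.
#'
#' Human recordings carry channels P7, P8, Cz, EyeAbove, EyeBelow with the
#' response dipole split between the contralateral mastoid and vertex so
#' that the montage difference recovers the template; cat recordings carry
#' Active and Reference channels.
#'
#' @param conditions Tibble with `condition` and `cor_masking_db`
#'   (0 for the unmasked reference condition).
#' @param species `"human"` or `"cat"`.
#' @param probe_level_db Probe level (dB SPL).
#' @param ref_level_db Growth-law reference level at which the unmasked
#'   template has its nominal amplitude (default = probe level).
#' @param growth_slope COR growth slope (dB/dB): default 0.16 (human) or
#'   0.34 (cat).
#' @param n_blocks Sweeps per condition (default 20).
#' @param probes_per_sweep Probes per sweep (default 13).
#' @param soa_s Probe onset asynchrony (s).
#' @param gap_s Silent gap between sweeps (s).
#' @param rate_hz Sampling rate (Hz; 250 is ample for a 1-20 Hz analysis
#'   band).
#' @param noise_rms_uv Background 1/f noise RMS per channel (uV).
#' @param channel_correlation Fraction of each scalp channel's noise power
#'   drawn from a shared background source (default 0.8). Low-frequency
#'   scalp noise is dominated by volume-conducted sources seen by every
#'   electrode, so channel differences cancel most of it; a montage
#'   difference of two channels has RMS
#'   `sqrt(2 * (1 - channel_correlation)) * noise_rms_uv`.
#' @param artifact_rate Fraction of epochs receiving an ocular artifact.
#' @param seed Integer seed.
#' @return List with `recording` (`data`, `rate_hz`, `stim_ear`),
#'   `triggers` (tibble: `time_s`, `sweep`, `probe_idx`, `condition`) and
#'   `truth` (tibble: `condition`, `cor_masking_db`, `amplitude_uv`,
#'   `scale`).
#' @export
sim_eeg_session <- function(conditions,
                            species = c("human", "cat"),
                            probe_level_db = 70,
                            ref_level_db = probe_level_db,
                            growth_slope = NULL,
                            n_blocks = 20,
                            probes_per_sweep = 13,
                            soa_s = 1,
                            gap_s = 1.2,
                            rate_hz = 250,
                            noise_rms_uv = 8,
                            channel_correlation = 0.8,
                            artifact_rate = 0,
                            seed = 1) {
  species <- match.arg(species)
  stopifnot(is.data.frame(conditions),
            all(c("condition", "cor_masking_db") %in% names(conditions)))
  if (is.null(growth_slope)) {
    growth_slope <- if (species == "human") 0.16 else 0.34
  }
  template <- eeg_template(species)
  # template support: 0..400 ms after onset
  tpl_times <- seq(0, 400, by = 1000 / rate_hz)
  tpl <- template_waveform(tpl_times, template)
  tpl_amp <- max(tpl) - min(tpl)

  n_cond <- nrow(conditions)
  sweep_dur <- probes_per_sweep * soa_s + gap_s
  n_sweeps <- n_cond * n_blocks
  lead_s <- 3 # quiet lead-in so early epochs fit their pre-onset window
  total_s <- lead_s + n_sweeps * sweep_dur + 3
  n_samples <- ceiling(total_s * rate_hz)

  # interleave conditions block by block
  sweep_cond <- rep(seq_len(n_cond), times = n_blocks)
  sweep_start <- lead_s + (seq_len(n_sweeps) - 1) * sweep_dur
  triggers <- bind_rows(lapply(seq_len(n_sweeps), function(s) {
    tibble(
      time_s = sweep_start[s] + (seq_len(probes_per_sweep) - 1) * soa_s,
      sweep = s,
      probe_idx = seq_len(probes_per_sweep),
      condition = conditions$condition[sweep_cond[s]]
    )
  }))

  truth <- conditions %>% mutate(
    scale = 10^((growth_slope * (probe_level_db - ref_level_db) +
                   .data$cor_masking_db) / 20),
    amplitude_uv = tpl_amp * .data$scale
  )

  signal_trace <- numeric(n_samples)
  for (i in seq_len(nrow(triggers))) {
    sc <- truth$scale[match(triggers$condition[i], truth$condition)]
    i0 <- round(triggers$time_s[i] * rate_hz) + 1
    idx <- i0 + seq_along(tpl) - 1
    signal_trace[idx] <- signal_trace[idx] + sc * tpl
  }

  channels <- if (species == "human") {
    c("P7", "P8", "Cz", "EyeAbove", "EyeBelow")
  } else {
    c("Active", "Reference")
  }
  data <- withr::with_seed(seed, {
    m <- matrix(0, nrow = length(channels), ncol = n_samples,
                dimnames = list(channels, NULL))
    common <- one_over_f_noise(
      n_samples, rate_hz, rms_uv = noise_rms_uv,
      seed = sample.int(.Machine$integer.max, 1)
    )
    for (j in seq_along(channels)) {
      own <- one_over_f_noise(
        n_samples, rate_hz, rms_uv = noise_rms_uv,
        seed = sample.int(.Machine$integer.max, 1)
      )
      m[j, ] <- sqrt(channel_correlation) * common +
        sqrt(1 - channel_correlation) * own
    }
    # split the response dipole across the montage pair
    if (species == "human") {
      m["P7", ] <- m["P7", ] + signal_trace / 2
      m["Cz", ] <- m["Cz", ] - signal_trace / 2
    } else {
      m["Active", ] <- m["Active", ] + signal_trace
    }
    if (artifact_rate > 0) {
      hit <- which(runif(nrow(triggers)) < artifact_rate)
      blink_t <- seq(-300, 300, by = 1000 / rate_hz)
      blink <- exp(-blink_t^2 / (2 * 80^2)) # slow ~190-ms FWHM deflection
      for (i in hit) {
        centre <- round((triggers$time_s[i] + runif(1, 0.05, 0.45)) * rate_hz)
        idx <- centre + seq_along(blink) - round(length(blink) / 2)
        idx <- idx[idx >= 1 & idx <= n_samples]
        bl <- blink[seq_along(idx)]
        if (species == "human") {
          m["EyeAbove", idx] <- m["EyeAbove", idx] + 150 * bl
          m["EyeBelow", idx] <- m["EyeBelow", idx] - 150 * bl
          m["P7", idx] <- m["P7", idx] + 30 * bl
          m["Cz", idx] <- m["Cz", idx] + 40 * bl
        } else {
          m["Active", idx] <- m["Active", idx] + 60 * blink[seq_along(idx)]
        }
      }
    }
    m
  })

  list(
    recording = list(data = data, rate_hz = rate_hz, stim_ear = "right"),
    triggers = triggers,
    truth = truth %>% select("condition", "cor_masking_db", "scale",
                             "amplitude_uv")
  )
}
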