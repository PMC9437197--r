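# Shared fixture helpers: everything is generated in code at test time.

# Power (linear) of a sampled signal inside a frequency band, from the FFT.
band_power <- function(signal, f_lo, f_hi) {
  x <- signal$samples
  n <- length(x)
  freqs <- (0:(n - 1)) * signal$rate_hz / n
  keep <- freqs <= signal$rate_hz / 2
  p <- Mod(fft(x))^2 / n^2
  sum(p[keep & freqs >= f_lo & freqs <= f_hi]) * 2 # one-sided
}

band_level_db <- function(signal, f_lo, f_hi) {
  10 * log10(band_power(signal, f_lo, f_hi) / (20e-6)^2)
}

# A minimal constructed epoch set: `amps` scales a two-peak template that
# has exact extrema at the given latencies.
toy_epochs <- function(amps, rate_hz = 500, window_ms = c(-200, 600),
                       n1_ms = 100, p2_ms = 180, noise_sd = 0) {
  times <- seq(window_ms[1], window_ms[2], by = 1000 / rate_hz)
  wf <- function(a) {
    a * (-4 * exp(-(times - n1_ms)^2 / (2 * 15^2)) +
           3 * exp(-(times - p2_ms)^2 / (2 * 15^2)))
  }
  data <- t(vapply(amps, function(a) {
    wf(a) + rnorm(length(times), 0, noise_sd)
  }, numeric(length(times))))
  structure(
    list(
      data = data, times_ms = times, rate_hz = rate_hz,
      info = tibble::tibble(
        time_s = seq_along(amps), rejected = FALSE,
        reject_reason = NA_character_
      )
    ),
    class = "cor_epochs"
  )
}

human_cfg <- function(...) recording_config("human", ...)
cat_cfg <- function(...) recording_config("cat", ...)
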