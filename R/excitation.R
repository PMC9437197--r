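#' Tonotopic array of roex-style filters
#'
#' A log-spaced channel array (default 2 channels per ERB from 500 to
#' 16,000 Hz, ERBs from [glasberg_moore_erb()]) of symmetric roex filters
#' with an optional level-dependent broadening of the lower skirt: with
#' coefficient `c_level > 0` the lower-side steepness of a channel is scaled
#' by `max(0.1, 1 - c_level * (L - 51) / 50)`, where `L` is the channel's
#' linear output level in dB SPL. This is an explicit, simplified surrogate
#' for a compressive nonlinear filterbank: it reproduces the upward spread
#' of excitation at high stimulus levels qualitatively, and makes no claim
#' to physiological accuracy.
#'
#' @param f_lo_hz,f_hi_hz Range of channel centre frequencies (Hz).
#' @param channels_per_erb Channel density (default 2 per ERB).
#' @param c_level Level-dependence coefficient (0 = linear; default 0.3).
#' @return A `channel_array` object with a `channels` tibble (`fc_hz`,
#'   `erb_hz`, `p`).
#' @export
channel_array <- function(f_lo_hz = 500, f_hi_hz = 16000,
                          channels_per_erb = 2, c_level = 0.3) {
  check_positive(f_lo_hz, "f_lo_hz")
  if (f_hi_hz <= f_lo_hz) abort("`f_hi_hz` must exceed `f_lo_hz`")
  if (c_level < 0) abort("`c_level` must be non-negative")
  fc <- f_lo_hz
  centres <- numeric(0)
  while (fc <= f_hi_hz) {
    centres <- c(centres, fc)
    fc <- fc + glasberg_moore_erb(fc) / channels_per_erb
  }
  erb <- glasberg_moore_erb(centres)
  structure(
    list(
      channels = tibble(fc_hz = centres, erb_hz = erb, p = 4 * centres / erb),
      c_level = c_level
    ),
    class = "channel_array"
  )
}

#' @export
print.channel_array <- function(x, ...) {
  cat(sprintf(
    "<channel_array> %d channels, %.0f-%.0f Hz, c = %g\n",
    nrow(x$channels), min(x$channels$fc_hz), max(x$channels$fc_hz), x$c_level
  ))
  invisible(x)
}

#' Stimulus spectrum description
#'
#' A stimulus is described by tonal lines and/or flat spectral bands.
#'
#' @param lines Tibble with `freq_hz`, `level_db_spl` (one row per tone), or
#'   `NULL`.
#' @param bands Tibble with `f_lo_hz`, `f_hi_hz`, `density_db_hz` (spectrum
#'   level), or `NULL`.
#' @return A `stim_spectrum` object.
#' @export
stim_spectrum <- function(lines = NULL, bands = NULL) {
  if (is.null(lines) && is.null(bands)) abort("empty spectrum")
  if (!is.null(lines)) stopifnot(all(c("freq_hz", "level_db_spl") %in% names(lines)))
  if (!is.null(bands)) {
    stopifnot(all(c("f_lo_hz", "f_hi_hz", "density_db_hz") %in% names(bands)))
  }
  structure(list(lines = lines, bands = bands), class = "stim_spectrum")
}

#' Spectrum of a band-limited noise masker
#'
#' @param spec A [band_spec()] or [notch_spec()].
#' @return A [stim_spectrum()] with the masker's flat band(s) at the
#'   spectrum level implied by the overall level and total bandwidth.
#' @export
masker_spectrum <- function(spec) {
  if (inherits(spec, "band_spec")) {
    bw <- spec$f_hi_hz - spec$f_lo_hz
    stim_spectrum(bands = tibble(
      f_lo_hz = spec$f_lo_hz, f_hi_hz = spec$f_hi_hz,
      density_db_hz = spec$level_db_spl - power_to_db(bw)
    ))
  } else if (inherits(spec, "notch_spec")) {
    b <- spec$bands
    total_bw <- sum(b$f_hi_hz - b$f_lo_hz)
    stim_spectrum(bands = tibble(
      f_lo_hz = b$f_lo_hz, f_hi_hz = b$f_hi_hz,
      density_db_hz = spec$level_db_spl - power_to_db(total_bw)
    ))
  } else {
    abort("`spec` must be a band_spec or notch_spec")
  }
}

# Filter output power (linear) of one channel for a spectrum, with possibly
# different steepness on the lower (f < fc) and upper (f > fc) sides.
channel_power <- function(fc, p_lo, p_hi, spectrum) {
  total <- 0
  if (!is.null(spectrum$lines)) {
    f <- spectrum$lines$freq_hz
    g <- abs(f - fc) / fc
    p_side <- ifelse(f < fc, p_lo, p_hi)
    w <- (1 + p_side * g) * exp(-p_side * g)
    total <- total + sum(w * db_to_power(spectrum$lines$level_db_spl))
  }
  if (!is.null(spectrum$bands)) {
    for (i in seq_len(nrow(spectrum$bands))) {
      f1 <- spectrum$bands$f_lo_hz[i]
      f2 <- spectrum$bands$f_hi_hz[i]
      dens <- db_to_power(spectrum$bands$density_db_hz[i])
      area <- 0
      if (f1 < fc) {
        hi <- min(f2, fc)
        area <- area + roex_band_integral(p_lo, (fc - hi) / fc, (fc - f1) / fc)
      }
      if (f2 > fc) {
        lo <- max(f1, fc)
        area <- area + roex_band_integral(p_hi, (lo - fc) / fc, (f2 - fc) / fc)
      }
      total <- total + dens * fc * area
    }
  }
  total
}

#' Excitation pattern of a stimulus across the channel array
#'
#' Each channel's output is the filter-weighted power integral of the
#' stimulus spectrum. With `c_level > 0` the lower-side steepness is first
#' relaxed according to the channel's linear output level (see
#' [channel_array()]), which broadens excitation toward higher channel
#' frequencies ("upward spread") for intense low-frequency input.
#'
#' @param spectrum A [stim_spectrum()] (or a masker spec coerced with
#'   [masker_spectrum()]).
#' @param array A [channel_array()].
#' @return An `excitation_pattern` tibble: `fc_hz`, `level_db` (channel
#'   output, dB SPL).
#' @export
excitation <- function(spectrum, array) {
  if (inherits(spectrum, c("band_spec", "notch_spec"))) {
    spectrum <- masker_spectrum(spectrum)
  }
  stopifnot(inherits(spectrum, "stim_spectrum"), inherits(array, "channel_array"))
  ch <- array$channels
  out <- vapply(seq_len(nrow(ch)), function(i) {
    fc <- ch$fc_hz[i]
    p <- ch$p[i]
    pw <- channel_power(fc, p, p, spectrum)
    if (array$c_level > 0 && pw > 0) {
      l0 <- power_to_db(pw) # linear-pass output level, dB SPL
      scale <- max(0.1, 1 - array$c_level * (l0 - 51) / 50)
      pw <- channel_power(fc, p * scale, p, spectrum)
    }
    pw
  }, numeric(1))
  structure(
    tibble(fc_hz = ch$fc_hz, level_db = power_to_db(pmax(out, 1e-30))),
    class = c("excitation_pattern", class(tibble())),
    c_level = array$c_level
  )
}

#' Generative masking law from filtered masker power
#'
#' A simple, explicitly non-physiological rule used to drive the synthetic
#' EEG generator: the masking (equivalent reduction in probe level, dB) is
#' the masker power at the output of the channel centred nearest the probe,
#' plus a detection offset, minus the probe level, floored at zero. Silence
#' produces zero masking, and masking decreases as the probe moves away
#' from a narrowband masker.
#'
#' @param probe A [probe_spec()].
#' @param masker A [band_spec()], [notch_spec()], [stim_spectrum()] or
#'   `NULL` (silence).
#' @param array A [channel_array()].
#' @param offset_db Detection offset (dB); the default 30 dB puts the
#'   centred-probe masking in the tens of dB, the order observed with
#'   near-centre maskers at a +10 dB probe-to-masker ratio.
#' @return Masking in dB (>= 0).
#' @export
predicted_masking <- function(probe, masker, array, offset_db = 30) {
  stopifnot(inherits(probe, "probe_spec"))
  if (is.null(masker)) return(0)
  pat <- excitation(masker, array)
  i <- which.min(abs(pat$fc_hz - probe$freq_hz))
  max(0, offset_db + pat$level_db[i] - probe$level_db_spl)
}
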