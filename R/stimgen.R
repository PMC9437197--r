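#' Geometric band edges of a noise masker
#'
#' Brick-wall cutoff frequencies of a band geometrically centred on
#' `centre_hz` with a width of `width_oct` octaves, i.e.
#' `centre * 2^(-width/2)` and `centre * 2^(+width/2)`. The geometric mean of
#' the edges equals the centre frequency.
#'
#' @param centre_hz Geometric centre frequency (Hz).
#' @param width_oct Bandwidth in octaves (0 gives a zero-width band).
#' @return Named numeric vector with elements `f_lo_hz` and `f_hi_hz`.
#' @examples
#' band_edges(4000, 1 / 8) # 3830 to 4177 Hz
#' band_edges(8000, 1)     # 5657 to 11314 Hz
#' @export
band_edges <- function(centre_hz, width_oct) {
  check_positive(centre_hz, "centre_hz")
  if (!is.numeric(width_oct) || !is.finite(width_oct) || width_oct < 0) {
    abort("`width_oct` must be non-negative and finite")
  }
  c(
    f_lo_hz = centre_hz * 2^(-width_oct / 2),
    f_hi_hz = centre_hz * 2^(+width_oct / 2)
  )
}

#' Specification of a band-limited noise masker
#'
#' @param centre_hz Geometric centre frequency (Hz).
#' @param width_oct Bandwidth in octaves.
#' @param level_db_spl Overall RMS level (dB SPL re 20 uPa).
#' @return A `band_spec` object; a list with the centre, width, derived
#'   brick-wall edges and level.
#' @examples
#' band_spec(8000, 1 / 8, 65)
#' @export
band_spec <- function(centre_hz, width_oct, level_db_spl) {
  edges <- band_edges(centre_hz, width_oct)
  structure(
    list(
      centre_hz = centre_hz, width_oct = width_oct,
      f_lo_hz = unname(edges["f_lo_hz"]), f_hi_hz = unname(edges["f_hi_hz"]),
      level_db_spl = level_db_spl
    ),
    class = "band_spec"
  )
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf(
    "<band_spec> %g oct at %g Hz [%.0f-%.0f Hz], %g dB SPL\n",
    x$width_oct, x$centre_hz, x$f_lo_hz, x$f_hi_hz, x$level_db_spl
  ))
  invisible(x)
}

#' Specification of a notched-noise masker
#'
#' Two flat flanking bands around a spectral notch. With `delta_f_frac = 0`
#' the bands abut at the centre frequency and together reproduce the
#' reference band (1 octave by default) exactly. As the notch widens, each
#' flanking band keeps its width in Hz constant (equal to the corresponding
#' half of the reference band) and is shifted outward: the lower band ends
#' at `centre * (1 - delta_f)` and the upper band starts at
#' `centre * (1 + delta_f)`.
#'
#' @param centre_hz Centre frequency of the notch (Hz).
#' @param delta_f_frac Notch half-width as a fraction of the centre frequency
#'   (0 to 0.3 in the reference experiments; must be `< 0.5`).
#' @param level_db_spl Overall RMS level of the two bands together (dB SPL).
#'   Because the total bandwidth in Hz is independent of the notch width,
#'   holding the overall level fixed also holds the spectrum level fixed.
#' @param ref_width_oct Width (octaves) of the unnotched reference band.
#' @return A `notch_spec` object containing a `bands` tibble with columns
#'   `f_lo_hz`, `f_hi_hz`.
#' @examples
#' notch_spec(4000, 0.3, 67.9)
#' @export
notch_spec <- function(centre_hz, delta_f_frac, level_db_spl,
                       ref_width_oct = 1) {
  check_positive(centre_hz, "centre_hz")
  if (delta_f_frac < 0 || delta_f_frac >= 0.5) {
    abort("`delta_f_frac` must be in [0, 0.5)")
  }
  bands <- notch_bands(centre_hz, delta_f_frac, ref_width_oct)
  if (any(bands$f_lo_hz <= 0)) abort("lower flanking band extends below 0 Hz")
  structure(
    list(
      centre_hz = centre_hz, delta_f_frac = delta_f_frac,
      bands = bands, level_db_spl = level_db_spl,
      ref_width_oct = ref_width_oct
    ),
    class = "notch_spec"
  )
}

#' Flanking-band geometry of a notched-noise masker
#'
#' @inheritParams notch_spec
#' @return Tibble with one row per flanking band (`side`, `f_lo_hz`,
#'   `f_hi_hz`).
#' @export
notch_bands <- function(centre_hz, delta_f_frac, ref_width_oct = 1) {
  edges <- band_edges(centre_hz, ref_width_oct)
  w_lo <- centre_hz - edges[["f_lo_hz"]] # width of lower half, Hz
  w_hi <- edges[["f_hi_hz"]] - centre_hz # width of upper half, Hz
  lo_hi <- centre_hz * (1 - delta_f_frac)
  hi_lo <- centre_hz * (1 + delta_f_frac)
  tibble(
    side = c("lower", "upper"),
    f_lo_hz = c(lo_hi - w_lo, hi_lo),
    f_hi_hz = c(lo_hi, hi_lo + w_hi)
  )
}

#' Specification of a ramped tone probe
#'
#' Species presets follow the reference paradigms: cat probes use 5-ms
#' cosine-squared ramps, human probes 2-ms sine-squared ramps (the two ramp
#' shapes are the same raised-cosine gate; both names are accepted).
#'
#' @param freq_hz Tone frequency (Hz).
#' @param level_db_spl Steady-state RMS level (dB SPL).
#' @param duration_ms Total duration including ramps (default 50 ms).
#' @param ramp_ms On/off ramp duration; default from `species`.
#' @param ramp_shape `"cosine-squared"` or `"sine-squared"`.
#' @param species `"cat"` or `"human"`, sets ramp defaults.
#' @return A `probe_spec` object.
#' @examples
#' probe_spec(8000, 75, species = "cat")
#' probe_spec(4000, 70, species = "human")
#' @export
probe_spec <- function(freq_hz, level_db_spl, duration_ms = 50,
                       ramp_ms = NULL, ramp_shape = NULL,
                       species = c("cat", "human")) {
  species <- match.arg(species)
  check_positive(freq_hz, "freq_hz")
  if (is.null(ramp_ms)) ramp_ms <- if (species == "cat") 5 else 2
  if (is.null(ramp_shape)) {
    ramp_shape <- if (species == "cat") "cosine-squared" else "sine-squared"
  }
  ramp_shape <- match.arg(ramp_shape, c("cosine-squared", "sine-squared"))
  if (duration_ms <= 2 * ramp_ms) {
    abort("`duration_ms` must exceed twice `ramp_ms`")
  }
  structure(
    list(
      freq_hz = freq_hz, level_db_spl = level_db_spl,
      duration_ms = duration_ms, ramp_ms = ramp_ms,
      ramp_shape = ramp_shape, species = species
    ),
    class = "probe_spec"
  )
}

#' Sampled acoustic signal
#'
#' Container for a pressure waveform in pascal, calibrated so that a digital
#' RMS of `20e-6 * 10^(L/20)` corresponds to `L` dB SPL.
#'
#' @param samples Numeric waveform (Pa).
#' @param rate_hz Sampling rate (Hz).
#' @param level_db_spl Target calibration level, if any.
#' @param meta List of generation metadata (spec, seed, ...).
#' @return A `sampled_signal` object.
#' @export
sampled_signal <- function(samples, rate_hz, level_db_spl = NA_real_,
                           meta = list()) {
  structure(
    list(
      samples = samples, rate_hz = rate_hz,
      level_db_spl = level_db_spl, meta = meta
    ),
    class = "sampled_signal"
  )
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf(
    "<sampled_signal> %.3f s at %g Hz, RMS %.1f dB SPL\n",
    length(x$samples) / x$rate_hz, x$rate_hz, rms_db_spl(x$samples)
  ))
  invisible(x)
}

#' Measured RMS level of a sampled signal
#'
#' @param signal A [sampled_signal()].
#' @return RMS level in dB SPL.
#' @export
signal_level_db <- function(signal) rms_db_spl(signal$samples)

# Frequency-domain synthesis of a noise with a prescribed one-sided
# amplitude profile: even-length real spectrum, uniform random phases in
# (-pi, pi], DC and Nyquist bins zero.
synth_from_amplitude <- function(amp_fn, duration_s, rate_hz, seed) {
  n <- 2 * ceiling(duration_s * rate_hz / 2) # force even length
  freqs <- (1:(n / 2 - 1)) * rate_hz / n     # positive bins excl. Nyquist
  amp <- amp_fn(freqs)
  phases <- withr::with_seed(seed, runif(length(freqs), -pi, pi))
  pos <- amp * exp(1i * phases)
  full <- c(0, pos, 0, Conj(rev(pos)))
  x <- Re(fft(full, inverse = TRUE)) / n
  list(samples = x, n = n)
}

calibrate_rms <- function(x, target_db_spl) {
  r <- rms(x)
  if (r == 0) abort("cannot calibrate an all-zero signal")
  x * spl_to_rms_pa(target_db_spl) / r
}

#' Synthesize a band-limited noise masker
#'
#' Created in the frequency domain with a flat amplitude spectrum and random
#' phase spectrum between the brick-wall cutoffs of the spec, then scaled to
#' the requested overall RMS level.
#'
#' @param spec A [band_spec()].
#' @param duration_s Duration (s).
#' @param rate_hz Sampling rate (Hz); must exceed twice the upper cutoff.
#' @param seed Integer seed; the waveform is deterministic given the seed.
#' @return A [sampled_signal()].
#' @examples
#' x <- make_band_noise(band_spec(8000, 1 / 8, 65), 0.5, 32000, seed = 1)
#' signal_level_db(x)
#' @export
make_band_noise <- function(spec, duration_s, rate_hz, seed) {
  stopifnot(inherits(spec, "band_spec"))
  if (rate_hz <= 2 * spec$f_hi_hz) {
    abort("sampling rate must exceed twice the upper band edge")
  }
  s <- synth_from_amplitude(
    function(f) as.numeric(f >= spec$f_lo_hz & f <= spec$f_hi_hz),
    duration_s, rate_hz, seed
  )
  sampled_signal(
    calibrate_rms(s$samples, spec$level_db_spl), rate_hz,
    level_db_spl = spec$level_db_spl, meta = list(spec = spec, seed = seed)
  )
}

#' Synthesize a pink-noise masker
#'
#' Pink noise (equal energy per octave) with brick-wall band edges, shaped in
#' the frequency domain with amplitude proportional to `1/sqrt(f)`. The level
#' is specified per 1/6th octave, the convention used when the pink noise
#' serves as a low-frequency masker of quadratic distortion products: in the
#' reference paradigm its level per 1/6 octave was 25.3 dB below the overall
#' level of the 1/8th-octave masker.
#'
#' @param f_lo_hz,f_hi_hz Passband edges (Hz).
#' @param level_per_sixth_oct_db Level within any 1/6-octave slice (dB SPL).
#' @param duration_s Duration (s).
#' @param rate_hz Sampling rate (Hz).
#' @param seed Integer seed.
#' @return A [sampled_signal()].
#' @export
make_pink_noise <- function(f_lo_hz, f_hi_hz, level_per_sixth_oct_db,
                            duration_s, rate_hz, seed) {
  check_positive(f_lo_hz, "f_lo_hz")
  if (f_hi_hz <= f_lo_hz) abort("`f_hi_hz` must exceed `f_lo_hz`")
  if (rate_hz <= 2 * f_hi_hz) {
    abort("sampling rate must exceed twice the upper band edge")
  }
  s <- synth_from_amplitude(
    function(f) ifelse(f >= f_lo_hz & f <= f_hi_hz, 1 / sqrt(f), 0),
    duration_s, rate_hz, seed
  )
  # Equal energy per octave: total power = (power per 1/6 oct) * 6 * octaves.
  n_oct <- log2(f_hi_hz / f_lo_hz)
  total_db <- level_per_sixth_oct_db + power_to_db(6 * n_oct)
  sampled_signal(
    calibrate_rms(s$samples, total_db), rate_hz,
    level_db_spl = total_db,
    meta = list(
      f_lo_hz = f_lo_hz, f_hi_hz = f_hi_hz,
      level_per_sixth_oct_db = level_per_sixth_oct_db, seed = seed
    )
  )
}

#' Synthesize a notched-noise masker
#'
#' Two flat flanking bands with constant width in Hz around a spectral notch
#' (see [notch_spec()]), synthesized in the frequency domain and calibrated
#' to the spec's overall level. With `delta_f_frac = 0` the output is
#' distributionally identical to the unnotched reference band.
#'
#' @param spec A [notch_spec()].
#' @inheritParams make_band_noise
#' @return A [sampled_signal()].
#' @export
make_notched_noise <- function(spec, duration_s, rate_hz, seed) {
  stopifnot(inherits(spec, "notch_spec"))
  if (rate_hz <= 2 * max(spec$bands$f_hi_hz)) {
    abort("sampling rate must exceed twice the upper band edge")
  }
  b <- spec$bands
  s <- synth_from_amplitude(
    function(f) {
      as.numeric((f >= b$f_lo_hz[1] & f <= b$f_hi_hz[1]) |
                   (f >= b$f_lo_hz[2] & f <= b$f_hi_hz[2]))
    },
    duration_s, rate_hz, seed
  )
  sampled_signal(
    calibrate_rms(s$samples, spec$level_db_spl), rate_hz,
    level_db_spl = spec$level_db_spl, meta = list(spec = spec, seed = seed)
  )
}

#' Synthesize a ramped tone probe
#'
#' A sinusoid gated with raised-cosine onset and offset ramps. The
#' steady-state RMS (between ramps) is calibrated to the spec level.
#'
#' @param spec A [probe_spec()].
#' @param rate_hz Sampling rate (Hz).
#' @param phase Starting phase (radians).
#' @return A [sampled_signal()].
#' @export
make_tone_probe <- function(spec, rate_hz, phase = 0) {
  stopifnot(inherits(spec, "probe_spec"))
  if (rate_hz <= 2 * spec$freq_hz) {
    abort("sampling rate must exceed twice the probe frequency")
  }
  n <- round(spec$duration_ms / 1000 * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  amp <- sqrt(2) * spl_to_rms_pa(spec$level_db_spl)
  x <- amp * sin(2 * pi * spec$freq_hz * t + phase)
  n_ramp <- round(spec$ramp_ms / 1000 * rate_hz)
  if (n_ramp > 0) {
    # cos^2 and sin^2 ramps are the same raised-cosine gate
    ramp <- sin(seq(0, pi / 2, length.out = n_ramp))^2
    x[1:n_ramp] <- x[1:n_ramp] * ramp
    x[(n - n_ramp + 1):n] <- x[(n - n_ramp + 1):n] * rev(ramp)
  }
  sampled_signal(x, rate_hz,
    level_db_spl = spec$level_db_spl, meta = list(spec = spec)
  )
}

#' Level offset equalizing masker energy through an auditory filter
#'
#' Offset (dB) to add to the wide masker so that a rectangular filter of
#' width `erb_hz` centred on the shared centre frequency passes the same
#' power from both maskers. A band narrower than the filter passes fully; in
#' the reference experiments this gives the 1-octave masker a level 7.9 dB
#' above the 1/8th-octave masker at 4 kHz (human, 456-Hz ERB) and 8.0 dB at
#' 8 kHz (888-Hz human-sized ERB).
#'
#' @param narrow,wide [band_spec()] objects sharing a centre frequency.
#' @param erb_hz Equivalent rectangular bandwidth of the filter (Hz).
#' @return Level offset in dB (wide re narrow).
#' @examples
#' equalize_masker_level(
#'   band_spec(4000, 1 / 8, 60), band_spec(4000, 1, 60),
#'   erb_hz = glasberg_moore_erb(4000)
#' )
#' @export
equalize_masker_level <- function(narrow, wide, erb_hz) {
  stopifnot(inherits(narrow, "band_spec"), inherits(wide, "band_spec"))
  if (abs(narrow$centre_hz - wide$centre_hz) > 1e-6 * narrow$centre_hz) {
    abort("both bands must share a centre frequency")
  }
  check_positive(erb_hz, "erb_hz")
  fc <- narrow$centre_hz
  frac <- function(b) {
    bw <- b$f_hi_hz - b$f_lo_hz
    overlap_width(b$f_lo_hz, b$f_hi_hz, fc - erb_hz / 2, fc + erb_hz / 2) / bw
  }
  power_to_db(frac(narrow) / frac(wide))
}
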