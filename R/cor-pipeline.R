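#' Species-specific COR analysis configuration
#'
#' Bundles the preprocessing and peak-picking parameters for cortical onset
#' response (COR) extraction. The two presets share one code path and differ
#' only in configuration:
#'
#' * `human`: contralateral-mastoid-minus-vertex montage, 1-20 Hz FIR
#'   bandpass (1-Hz transition, 2-s padding), epochs -200 to 600 ms,
#'   baseline correction over -200 to 0 ms, ocular-artifact rejection at
#'   z > 4 on the below-minus-above-eye channel, N1 = minimum in 50-150 ms,
#'   P2 = maximum in 100-200 ms, amplitude = P2 - N1.
#' * `cat`: single derived channel, 3-20 Hz bandpass, analysis window 0-120
#'   ms (no baseline), rejection of epochs exceeding 4x the RMS background
#'   in the analysis window, slope-reversal peak picking with P1 in 15-55 ms
#'   and N1 in 55-120 ms, amplitude = P1 - N1.
#'
#' @param species `"cat"` or `"human"`.
#' @param ... Named overrides for any configuration field.
#' @return A `recording_config` list.
#' @export
recording_config <- function(species = c("human", "cat"), ...) {
  species <- match.arg(species)
  cfg <- if (species == "human") {
    list(
      species = "human",
      filter_band_hz = c(1, 20),
      transition_hz = 1,
      pad_s = 2,
      epoch_window_ms = c(-200, 600),
      baseline_window_ms = c(-200, 0),
      analysis_window_ms = c(0, 600),
      peak_windows_ms = list(N1 = c(50, 150), P2 = c(100, 200)),
      peak_polarity = c(N1 = -1, P2 = +1),
      amplitude_rule = c(positive = "P2", negative = "N1"),
      peak_method = "extremum",
      artifact_rule = "eye_z",
      artifact_z = 4,
      smooth_ms = 0
    )
  } else {
    list(
      species = "cat",
      filter_band_hz = c(3, 20),
      transition_hz = 1,
      pad_s = 2,
      epoch_window_ms = c(-50, 250),
      baseline_window_ms = NULL, # cat preset: no baseline correction
      analysis_window_ms = c(0, 120),
      peak_windows_ms = list(P1 = c(15, 55), N1 = c(55, 120)),
      peak_polarity = c(P1 = +1, N1 = -1),
      amplitude_rule = c(positive = "P1", negative = "N1"),
      peak_method = "slope_reversal",
      artifact_rule = "rms_window",
      artifact_rms_mult = 4,
      smooth_ms = 2 # boxcar before slope-reversal detection
    )
  }
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "recording_config")
}

#' Derive a single analysis channel from a multichannel recording
#'
#' Computes the difference between two named channels, e.g. the
#' contralateral mastoid minus vertex montage used for human COR recordings
#' (P7 - Cz for right-ear stimulation, P8 - Cz for left-ear).
#'
#' @param recording List with elements `data` (channels x samples matrix
#'   with rownames), `rate_hz`, and optionally `stim_ear` (`"left"` or
#'   `"right"`).
#' @param montage Character vector of two channel names `c(active, ref)`,
#'   or `"auto"` to pick the contralateral mastoid (P7/P8) minus Cz from
#'   `stim_ear`.
#' @return Numeric vector, the difference trace.
#' @export
derive_channel <- function(recording, montage = "auto") {
  stopifnot(is.matrix(recording$data))
  if (identical(montage, "auto")) {
    ear <- recording$stim_ear
    if (is.null(ear)) abort("`stim_ear` needed for montage = \"auto\"")
    montage <- c(if (ear == "right") "P7" else "P8", "Cz")
  }
  missing <- setdiff(montage, rownames(recording$data))
  if (length(missing) > 0) {
    abort(paste("channel(s) not in recording:", paste(missing, collapse = ", ")))
  }
  recording$data[montage[1], ] - recording$data[montage[2], ]
}

#' Cut a continuous trace into triggered epochs
#'
#' @param trace Numeric vector (single channel).
#' @param triggers Tibble with `time_s` (probe onsets) and optionally
#'   `sweep`, `probe_idx` and condition columns, which are carried into the
#'   epoch info.
#' @param rate_hz Sampling rate of `trace`.
#' @param window_ms Epoch window re probe onset, `c(from, to)`; sample 0 is
#'   the onset sample (inclusive).
#' @param drop_first_per_sweep If `TRUE` and `triggers$probe_idx` exists,
#'   the first probe of each sweep is dropped (its onset coincides with the
#'   masker onset, so its response is contaminated by the masker onset
#'   response).
#' @return A `cor_epochs` object: epochs x time matrix plus `times_ms`,
#'   `rate_hz` and an `info` tibble (one row per epoch, with `rejected` and
#'   `reject_reason` columns).
#' @export
epoch_trace <- function(trace, triggers, rate_hz, window_ms = c(-200, 600),
                        drop_first_per_sweep = FALSE) {
  stopifnot(is.data.frame(triggers), "time_s" %in% names(triggers))
  trg <- triggers
  if (is.unsorted(trg$time_s)) trg <- arrange(trg, .data$time_s)
  if (drop_first_per_sweep) {
    if (!"probe_idx" %in% names(trg)) {
      abort("`drop_first_per_sweep` needs a `probe_idx` trigger column")
    }
    trg <- filter(trg, .data$probe_idx != 1)
  }
  i0 <- round(trg$time_s * rate_hz) + 1 # onset sample, 1-based
  from <- round(window_ms[1] / 1000 * rate_hz)
  to <- round(window_ms[2] / 1000 * rate_hz)
  if (any(i0 + from < 1) || any(i0 + to > length(trace))) {
    abort("epoch window extends beyond the recording")
  }
  idx <- outer(i0, from:to, "+")
  data <- matrix(trace[idx], nrow = length(i0))
  info <- as_tibble(trg)
  info$rejected <- FALSE
  info$reject_reason <- NA_character_
  structure(
    list(
      data = data,
      times_ms = (from:to) / rate_hz * 1000,
      rate_hz = rate_hz,
      info = info
    ),
    class = "cor_epochs"
  )
}

#' @export
print.cor_epochs <- function(x, ...) {
  cat(sprintf(
    "<cor_epochs> %d epochs x %d samples (%.0f to %.0f ms at %g Hz), %d rejected\n",
    nrow(x$data), ncol(x$data), min(x$times_ms), max(x$times_ms),
    x$rate_hz, sum(x$info$rejected)
  ))
  invisible(x)
}

#' @describeIn epoch_trace Long-format view of an epoch set: one row per
#'   epoch x sample, with the epoch info joined on.
#' @param x A `cor_epochs` object.
#' @param ... Unused.
#' @export
tidy.cor_epochs <- function(x, ...) {
  long <- tibble(
    epoch = rep(seq_len(nrow(x$data)), times = ncol(x$data)),
    time_ms = rep(x$times_ms, each = nrow(x$data)),
    amplitude_uv = as.vector(x$data)
  )
  info <- x$info %>% mutate(epoch = row_number())
  left_join(long, info, by = "epoch") %>% arrange(.data$epoch, .data$time_ms)
}

# Zero-phase FIR bandpass via a linear-phase Hamming-window design applied
# to a reflection-padded signal, with the group delay removed. The order is
# set from the transition bandwidth (Hamming: ~3.3/N normalized), giving
# > 40 dB attenuation one transition-width beyond the band edges.
fir_design <- function(rate_hz, band_hz, transition_hz = 1) {
  nyq <- rate_hz / 2
  if (band_hz[2] >= nyq) abort("upper band edge must be below Nyquist")
  n_ord <- ceiling(3.3 * rate_hz / transition_hz)
  if (n_ord %% 2 == 1) n_ord <- n_ord + 1 # even order -> odd length, type I
  signal::fir1(n_ord, band_hz / nyq, type = "pass")
}

fir_bandpass_trace <- function(x, rate_hz, band_hz, transition_hz = 1,
                               pad_s = 2) {
  b <- fir_design(rate_hz, band_hz, transition_hz)
  n_ord <- length(b) - 1
  n_pad <- round(pad_s * rate_hz)
  # reflection padding; repeated (triangular) reflection supports pads
  # longer than the epoch itself
  n <- length(x)
  reflect <- function(i) {
    m <- (i - 1) %% (2 * n - 2)
    ifelse(m < n, m + 1, 2 * n - 1 - m)
  }
  pad_l <- x[reflect(1 - seq_len(n_pad))]
  pad_r <- x[reflect(n + seq_len(n_pad))]
  xp <- c(rev(pad_l), x, pad_r, numeric(n_ord))
  y <- signal::fftfilt(b, xp)
  delay <- n_ord / 2
  y[(n_pad + delay + 1):(n_pad + delay + length(x))]
}

#' Bandpass-filter an epoch set
#'
#' Applies the configuration's zero-phase FIR bandpass to every epoch, with
#' reflection padding (`pad_s`, default 2 s) so that filter transients fall
#' outside the epoch. The human preset (1-20 Hz, 1-Hz transition) removes DC
#' and line components; the cat preset uses 3-20 Hz.
#'
#' @param epochs A `cor_epochs` object (or a `recording` list with a
#'   continuous trace in `$trace`).
#' @param config A [recording_config()].
#' @return The filtered `cor_epochs`.
#' @export
bandpass_epochs <- function(epochs, config) {
  stopifnot(inherits(epochs, "cor_epochs"))
  epochs$data <- t(apply(epochs$data, 1, fir_bandpass_trace,
    rate_hz = epochs$rate_hz, band_hz = config$filter_band_hz,
    transition_hz = config$transition_hz, pad_s = config$pad_s
  ))
  epochs
}

window_index <- function(times_ms, window_ms) {
  which(times_ms >= window_ms[1] & times_ms <= window_ms[2])
}

#' Flag artifact epochs
#'
#' Pure flagging: surviving epochs are untouched and the flags (with
#' reasons) are recorded in the epoch info. Two rules are provided:
#'
#' * `rms_window` (cat preset): an epoch is rejected when its absolute
#'   amplitude within the analysis window exceeds `artifact_rms_mult` (4)
#'   times the RMS background level, where the background is the pooled RMS
#'   over all epochs' analysis windows.
#' * `eye_z` (human preset): a z-score is computed from the below-minus-
#'   above-eye difference trace over the whole recording; epochs containing
#'   samples with |z| > `artifact_z` (4) are rejected.
#'
#' @param epochs A `cor_epochs` object.
#' @param config A [recording_config()].
#' @param eye_trace Continuous eye-difference trace (same sampling as the
#'   recording), required for the `eye_z` rule.
#' @param eye_epochs Optionally, a `cor_epochs` of the eye trace epoched
#'   like `epochs` (computed internally from `eye_trace` otherwise).
#' @return The `cor_epochs` with `rejected` / `reject_reason` flags set.
#' @export
reject_artifacts <- function(epochs, config, eye_trace = NULL,
                             eye_epochs = NULL) {
  stopifnot(inherits(epochs, "cor_epochs"))
  rule <- config$artifact_rule
  if (rule == "rms_window") {
    idx <- window_index(epochs$times_ms, config$analysis_window_ms)
    win <- epochs$data[, idx, drop = FALSE]
    background_rms <- sqrt(mean(win^2))
    bad <- apply(abs(win), 1, max) > config$artifact_rms_mult * background_rms
    reason <- sprintf("peak > %gx RMS background", config$artifact_rms_mult)
  } else if (rule == "eye_z") {
    if (is.null(eye_epochs)) {
      if (is.null(eye_trace)) {
        abort("the eye_z rule needs `eye_trace` or `eye_epochs`")
      }
      z <- (eye_trace - mean(eye_trace)) / sd(eye_trace)
      eye_epochs <- epoch_trace(
        z, epochs$info, epochs$rate_hz,
        window_ms = range(epochs$times_ms)
      )
    }
    bad <- apply(abs(eye_epochs$data), 1, max) > config$artifact_z
    reason <- sprintf("eye-channel |z| > %g", config$artifact_z)
  } else {
    abort(paste("unknown artifact rule:", rule))
  }
  epochs$info$rejected <- epochs$info$rejected | bad
  epochs$info$reject_reason[bad] <- reason
  epochs
}

#' Average surviving epochs with optional baseline correction
#'
#' @param epochs A `cor_epochs` object (rejected epochs are excluded).
#' @param config A [recording_config()]; when the configuration has a
#'   baseline window (human preset: -200 to 0 ms) the mean over that window
#'   is subtracted from the averaged waveform.
#' @return A `cor_average` object: `waveform` (uV), `times_ms`, `rate_hz`,
#'   `n_epochs_used`, `config`.
#' @export
average_epochs <- function(epochs, config) {
  stopifnot(inherits(epochs, "cor_epochs"))
  keep <- !epochs$info$rejected
  if (!any(keep)) abort("all epochs rejected; nothing to average")
  wf <- colMeans(epochs$data[keep, , drop = FALSE])
  if (!is.null(config$baseline_window_ms)) {
    idx <- window_index(epochs$times_ms, config$baseline_window_ms)
    wf <- wf - mean(wf[idx])
  }
  structure(
    list(
      waveform = wf, times_ms = epochs$times_ms, rate_hz = epochs$rate_hz,
      n_epochs_used = sum(keep), config = config
    ),
    class = "cor_average"
  )
}

#' @export
print.cor_average <- function(x, ...) {
  cat(sprintf(
    "<cor_average> %d epochs averaged, %.0f to %.0f ms\n",
    x$n_epochs_used, min(x$times_ms), max(x$times_ms)
  ))
  invisible(x)
}

# First slope reversal of the requested polarity inside a window, after
# light boxcar smoothing: +1 looks for a local maximum (slope + to -), -1
# for a local minimum. Returns the sample index in the full waveform or NA.
find_slope_reversal <- function(wf, idx, polarity, smooth_n) {
  if (smooth_n > 1) {
    k <- rep(1 / smooth_n, smooth_n)
    wf <- as.numeric(stats::filter(wf, k, sides = 2))
  }
  d <- diff(wf)
  rev_pts <- integer(0)
  inner <- idx[idx > 1 & idx < length(wf)]
  for (i in inner) {
    s_prev <- d[i - 1]
    s_next <- d[i]
    if (is.na(s_prev) || is.na(s_next)) next
    ok <- if (polarity > 0) s_prev > 0 && s_next <= 0 else s_prev < 0 && s_next >= 0
    if (ok) rev_pts <- c(rev_pts, i)
  }
  if (length(rev_pts) == 0) NA_integer_ else rev_pts[1] # earliest in window
}

#' Extract COR peaks from an averaged waveform
#'
#' Applies the configuration's peak rule: the human preset takes the global
#' minimum (N1) and maximum (P2) within their latency windows; the cat
#' preset takes the earliest slope reversal of the correct polarity (P1
#' positive-going, N1 negative-going) within each window after a light
#' boxcar smoothing. The response amplitude is the positive peak minus the
#' negative peak (P2 - N1 or P1 - N1), in uV.
#'
#' @param average A `cor_average` from [average_epochs()].
#' @param config A [recording_config()] (defaults to the one stored in the
#'   average).
#' @return A `cor_result` tibble with one row per peak (`peak`,
#'   `latency_ms`, `amplitude_uv`, `found`) and attributes `amplitude_uv`
#'   (peak-to-peak) and `n_epochs_used`. Use [cor_amplitude()] to extract
#'   the scalar amplitude.
#' @export
pick_peaks <- function(average, config = average$config) {
  stopifnot(inherits(average, "cor_average"))
  wf <- average$waveform
  times <- average$times_ms
  smooth_n <- max(1, round(config$smooth_ms / 1000 * average$rate_hz))
  rows <- purrr::imap(config$peak_windows_ms, function(win, name) {
    idx <- window_index(times, win)
    if (length(idx) == 0) abort("peak window outside the epoch")
    pol <- config$peak_polarity[[name]]
    if (config$peak_method == "extremum") {
      i <- idx[if (pol > 0) which.max(wf[idx]) else which.min(wf[idx])]
    } else {
      i <- find_slope_reversal(wf, idx, pol, smooth_n)
    }
    if (is.na(i)) {
      tibble(
        peak = name, latency_ms = NA_real_, amplitude_uv = NA_real_,
        found = FALSE
      )
    } else {
      tibble(
        peak = name, latency_ms = times[i], amplitude_uv = wf[i], found = TRUE
      )
    }
  })
  res <- bind_rows(rows)
  pos <- res$amplitude_uv[res$peak == config$amplitude_rule[["positive"]]]
  neg <- res$amplitude_uv[res$peak == config$amplitude_rule[["negative"]]]
  amp <- if (all(res$found)) pos - neg else NA_real_
  structure(res,
    class = c("cor_result", class(res)),
    amplitude_uv = amp,
    n_epochs_used = average$n_epochs_used
  )
}

#' Peak-to-peak COR amplitude of a cor_result
#'
#' @param result A `cor_result` from [pick_peaks()].
#' @return Amplitude in uV (`NA` if a peak was not found).
#' @export
cor_amplitude <- function(result) attr(result, "amplitude_uv")

#' Masked response amplitude in dB re the unmasked condition
#'
#' @param masked_uv,unmasked_uv Peak-to-peak amplitudes (uV); both must be
#'   positive.
#' @return `20 * log10(masked / unmasked)` in dB (non-positive when the
#'   masker reduces the response).
#' @export
to_db_re_unmasked <- function(masked_uv, unmasked_uv) {
  if (any(!is.finite(masked_uv)) || any(!is.finite(unmasked_uv)) ||
      any(masked_uv <= 0) || any(unmasked_uv <= 0)) {
    abort("amplitudes must be positive and finite")
  }
  20 * log10(masked_uv / unmasked_uv)
}

#' Full COR extraction pipeline over conditions
#'
#' Runs montage derivation, epoching (dropping each sweep's first,
#' masker-coincident probe), bandpass filtering, artifact flagging,
#' averaging and peak picking separately for every condition in the trigger
#' table, and expresses masked amplitudes in dB re the reference condition.
#'
#' @param recording Recording list (`data` channels x samples, `rate_hz`,
#'   `stim_ear`); see [derive_channel()].
#' @param triggers Trigger tibble with `time_s`, `sweep`, `probe_idx` and a
#'   `condition` column.
#' @param config A [recording_config()].
#' @param montage Passed to [derive_channel()].
#' @param eye_montage Channel pair for the ocular artifact trace (human
#'   preset), default below-minus-above-eye.
#' @param ref_condition Condition label used as the unmasked reference for
#'   the dB column, or `NULL` to skip.
#' @param drop_first_per_sweep Drop each sweep's first probe (default TRUE).
#' @return Tibble with one row per condition: peak latencies/amplitudes,
#'   `amplitude_uv`, `n_epochs_used`, `n_epochs_rejected`, and
#'   `amplitude_db_re_unmasked` when a reference is given.
#' @export
cor_pipeline <- function(recording, triggers, config,
                         montage = "auto",
                         eye_montage = c("EyeBelow", "EyeAbove"),
                         ref_condition = NULL,
                         drop_first_per_sweep = TRUE) {
  trace <- derive_channel(recording, montage)
  eye_trace <- NULL
  if (config$artifact_rule == "eye_z") {
    eye_trace <- derive_channel(recording, eye_montage)
    eye_trace <- (eye_trace - mean(eye_trace)) / sd(eye_trace)
  }
  conditions <- unique(triggers$condition)
  rows <- lapply(conditions, function(cond) {
    trg <- filter(triggers, .data$condition == cond)
    ep <- epoch_trace(trace, trg, recording$rate_hz,
      window_ms = config$epoch_window_ms,
      drop_first_per_sweep = drop_first_per_sweep
    )
    ep <- bandpass_epochs(ep, config)
    eye_ep <- NULL
    if (config$artifact_rule == "eye_z") {
      eye_ep <- epoch_trace(eye_trace, ep$info, recording$rate_hz,
        window_ms = config$epoch_window_ms
      )
    }
    ep <- reject_artifacts(ep, config, eye_epochs = eye_ep)
    res <- pick_peaks(average_epochs(ep, config))
    peaks <- as_tibble(res)
    out <- tibble(
      condition = cond,
      amplitude_uv = cor_amplitude(res),
      n_epochs_used = attr(res, "n_epochs_used"),
      n_epochs_rejected = sum(ep$info$rejected)
    )
    for (i in seq_len(nrow(peaks))) {
      out[[paste0(peaks$peak[i], "_latency_ms")]] <- peaks$latency_ms[i]
      out[[paste0(peaks$peak[i], "_uv")]] <- peaks$amplitude_uv[i]
    }
    out
  })
  out <- bind_rows(rows)
  if (!is.null(ref_condition)) {
    ref <- out$amplitude_uv[out$condition == ref_condition]
    if (length(ref) != 1 || !is.finite(ref) || ref <= 0) {
      abort("reference condition missing or has no valid amplitude")
    }
    out <- out %>% mutate(
      amplitude_db_re_unmasked = to_db_re_unmasked(.data$amplitude_uv, ref)
    )
  }
  out
}
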