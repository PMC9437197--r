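# --- synthetic hold-release sessions and notched-noise thresholds ---------

#' Synthetic hold-release observer
#'
#' Parameters of a simulated go/no-go observer: a logistic psychometric
#' function for probe detection, a lapse rate, and an "impatience" hazard of
#' spontaneous pedal releases that grows with time into the hold (emulating
#' subjects increasingly eager for the reward), which produces false-alarm
#' rates that increase with hold time.
#'
#' @param midpoint_db Level of the detection-function midpoint (dB); with a
#'   steep slope and low false-alarm rate this is the observer's true
#'   threshold at the d' = 1 criterion.
#' @param slope_db Logistic width (dB).
#' @param lapse Probability of missing a detected probe anyway.
#' @param release_hazard_per_s Baseline spontaneous-release hazard (events
#'   per second at the start of the hold).
#' @param impatience Multiplicative hazard growth per second of elapsed
#'   hold.
#' @return A `synthetic_observer` object.
#' @export
synthetic_observer <- function(midpoint_db, slope_db = 2, lapse = 0,
                               release_hazard_per_s = 0.02,
                               impatience = 1.3) {
  structure(
    list(
      midpoint_db = midpoint_db, slope_db = slope_db, lapse = lapse,
      release_hazard_per_s = release_hazard_per_s, impatience = impatience
    ),
    class = "synthetic_observer"
  )
}

# Spontaneous release time (s re masker onset) under a piecewise-constant
# hazard growing per 1-s segment; Inf if no release before t_max.
sample_spontaneous_release <- function(observer, t_max) {
  t <- 0
  repeat {
    seg <- floor(t)
    lambda <- observer$release_hazard_per_s * observer$impatience^seg
    wait <- stats::rexp(1, rate = lambda)
    t_next <- min(seg + 1, t + wait)
    if (t + wait <= seg + 1) return(t + wait)
    t <- seg + 1
    if (t >= t_max) return(Inf)
  }
}

#' Simulate a hold-release detection session
#'
#' Each trial draws a hold time uniformly from `holds_s`, a possible
#' spontaneous (impatience-driven) release, and — if the pedal is still
#' held at probe onset — a detection governed by the observer's
#' psychometric function, with detected probes answered at a latency
#' uniform in 200-800 ms. The earlier of spontaneous release and detection
#' response determines the recorded latency.
#'
#' @param observer A [synthetic_observer()].
#' @param levels_db Probe levels to test (2-dB grid in the reference
#'   sessions).
#' @param n_trials_per_level Trials per probe level.
#' @param holds_s Candidate probe-onset delays (default 2, 3, 4, 5 s).
#' @param masker Condition label stored with the trials.
#' @param probe_freq_hz Probe frequency stored with the trials.
#' @param seed Integer seed.
#' @return List with `trials` (tibble: `session`, `hold_s`,
#'   `release_ms_re_probe`, `masker`, `probe_freq_hz`, `probe_level_db`)
#'   and `truth` (observer parameters; `threshold_db` = midpoint).
#' @export
sim_holdrelease_session <- function(observer, levels_db,
                                    n_trials_per_level = 30,
                                    holds_s = 2:5,
                                    masker = "masker",
                                    probe_freq_hz = 8000,
                                    seed = 1) {
  stopifnot(inherits(observer, "synthetic_observer"))
  grid <- tidyr::expand_grid(
    probe_level_db = levels_db,
    rep = seq_len(n_trials_per_level)
  )
  trials <- withr::with_seed(seed, {
    n <- nrow(grid)
    hold <- sample(holds_s, n, replace = TRUE)
    release <- vapply(seq_len(n), function(i) {
      h <- hold[i]
      t_spont <- sample_spontaneous_release(observer, h + 2)
      p_det <- (1 - observer$lapse) /
        (1 + exp(-(grid$probe_level_db[i] - observer$midpoint_db) /
                   observer$slope_db))
      t_det <- if (runif(1) < p_det) h + runif(1, 0.2, 0.8) else Inf
      t_rel <- min(t_spont, t_det)
      if (is.infinite(t_rel)) NA_real_ else (t_rel - h) * 1000
    }, numeric(1))
    tibble(
      session = 1L,
      hold_s = hold,
      release_ms_re_probe = release,
      masker = masker,
      probe_freq_hz = probe_freq_hz,
      probe_level_db = grid$probe_level_db
    )
  })
  list(
    trials = trials,
    truth = list(
      threshold_db = observer$midpoint_db,
      observer = observer
    )
  )
}

#' Simulate notched-noise thresholds from a known roex filter
#'
#' Generates per-subject detection thresholds at a set of notch widths from
#' the power-spectrum model with a known ERB and efficiency, plus
#' independent Gaussian measurement noise — ground truth for
#' [fit_roex()] / [bootstrap_erb()] recovery tests.
#'
#' @param true_erb_hz True equivalent rectangular bandwidth (Hz).
#' @param fc_hz Probe/centre frequency (Hz).
#' @param efficiency_k_db True detector efficiency (dB).
#' @param noise_sd_db SD of per-threshold Gaussian noise (dB).
#' @param n_subjects Number of subjects.
#' @param masker_level_db_spl Overall level of the unnotched masker band.
#' @param delta_f_fracs Notch widths (fractions of `fc_hz`).
#' @param ref_width_oct Reference band width (octaves).
#' @param seed Integer seed.
#' @return Tibble with `subject`, `delta_f_frac`, `threshold_db_spl`;
#'   attribute `truth` holds the generating parameters.
#' @export
sim_notch_thresholds <- function(true_erb_hz, fc_hz, efficiency_k_db,
                                 noise_sd_db, n_subjects,
                                 masker_level_db_spl,
                                 delta_f_fracs = c(0, 0.1, 0.2, 0.3),
                                 ref_width_oct = 1,
                                 seed = 1) {
  filt <- roex_filter(fc_hz, erb_hz = true_erb_hz)
  clean <- vapply(delta_f_fracs, function(d) {
    predict_notch_threshold(
      filt,
      notch_masker_bands(fc_hz, d, masker_level_db_spl, ref_width_oct),
      efficiency_k_db
    )
  }, numeric(1))
  out <- tidyr::expand_grid(
    subject = paste0("S", seq_len(n_subjects)),
    delta_f_frac = delta_f_fracs
  )
  out$threshold_db_spl <- rep(clean, times = n_subjects) +
    withr::with_seed(seed, rnorm(nrow(out), 0, noise_sd_db))
  attr(out, "truth") <- list(
    erb_hz = true_erb_hz, p = filt$p, efficiency_k_db = efficiency_k_db,
    clean_thresholds_db_spl = setNames(clean, delta_f_fracs)
  )
  out
}
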