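#' Glasberg-Moore equivalent rectangular bandwidth
#'
#' ERB of the normal human auditory filter as a function of centre frequency:
#' `ERB = 24.7 * (4.37 * f_kHz + 1)` Hz.
#'
#' @param f_hz Centre frequency (Hz).
#' @return ERB in Hz.
#' @examples
#' glasberg_moore_erb(4000) # ~456 Hz
#' glasberg_moore_erb(8000) # ~888 Hz
#' @export
glasberg_moore_erb <- function(f_hz) {
  check_positive(f_hz, "f_hz")
  24.7 * (4.37 * f_hz / 1000 + 1)
}

#' Power ratio of two ERBs
#'
#' `10 * log10(erb_a / erb_b)`: the extra broadband-noise power admitted by a
#' filter of width `erb_a` relative to one of width `erb_b`.
#'
#' @param erb_a_hz,erb_b_hz Bandwidths (Hz).
#' @return Ratio in dB.
#' @examples
#' erb_power_ratio(1087, 888) # ~0.9 dB
#' @export
erb_power_ratio <- function(erb_a_hz, erb_b_hz) {
  check_positive(erb_a_hz, "erb_a_hz")
  check_positive(erb_b_hz, "erb_b_hz")
  power_to_db(erb_a_hz / erb_b_hz)
}

#' Symmetric roex(p) auditory filter
#'
#' Rounded-exponential filter with weighting `W(g) = (1 + p*g) * exp(-p*g)`,
#' where `g = |f - fc| / fc` is the normalized deviation from the centre
#' frequency and `p` controls the steepness of the skirts. Its equivalent
#' rectangular bandwidth is `ERB = 4 * fc / p`.
#'
#' @param fc_hz Centre frequency (Hz).
#' @param p Steepness parameter (give either `p` or `erb_hz`).
#' @param erb_hz Equivalent rectangular bandwidth (Hz).
#' @return A `roex_filter` object.
#' @examples
#' roex_filter(4000, erb_hz = 456)
#' @export
roex_filter <- function(fc_hz, p = NULL, erb_hz = NULL) {
  check_positive(fc_hz, "fc_hz")
  if (is.null(p) && is.null(erb_hz)) abort("give `p` or `erb_hz`")
  if (is.null(p)) p <- 4 * fc_hz / erb_hz
  check_positive(p, "p")
  structure(
    list(fc_hz = fc_hz, p = p, erb_hz = 4 * fc_hz / p),
    class = "roex_filter"
  )
}

#' @export
print.roex_filter <- function(x, ...) {
  cat(sprintf(
    "<roex_filter> fc = %g Hz, p = %.2f, ERB = %.0f Hz\n",
    x$fc_hz, x$p, x$erb_hz
  ))
  invisible(x)
}

#' roex filter weight
#'
#' @param g Normalized deviation from the centre frequency, `|f - fc| / fc`
#'   (non-negative; symmetry is handled by the caller).
#' @param p Steepness parameter (> 0).
#' @return Weight in (0, 1], monotonically decreasing in `g`.
#' @examples
#' roex_weight(0.1, 20) # 3 * exp(-2)
#' @export
roex_weight <- function(g, p) {
  if (any(g < 0)) abort("`g` must be non-negative")
  check_positive(p, "p")
  (1 + p * g) * exp(-p * g)
}

#' Closed-form integral of the roex weight
#'
#' `integral of W(g) dg` from `g1` to `g2`, equal to
#' `((2 + p*g1) * exp(-p*g1) - (2 + p*g2) * exp(-p*g2)) / p`. The total area
#' over both filter skirts is `4/p = ERB/fc`.
#'
#' @param p Steepness parameter.
#' @param g1,g2 Integration limits, `0 <= g1 <= g2` (Inf allowed).
#' @return The band area (dimensionless).
#' @export
roex_band_integral <- function(p, g1, g2) {
  check_positive(p, "p")
  if (any(g1 < 0) || any(g2 < g1)) abort("need 0 <= g1 <= g2")
  term <- function(g) ifelse(is.infinite(g), 0, (2 + p * g) * exp(-p * g))
  (term(g1) - term(g2)) / p
}

# Masker power (dB, arbitrary reference) at the output of a roex filter, for
# a masker described by flat spectral bands. `bands` has columns f_lo_hz,
# f_hi_hz and density_db_hz (power spectrum level per Hz, in the same dB
# reference as the returned value).
filtered_masker_power_db <- function(filter, bands) {
  stopifnot(inherits(filter, "roex_filter"))
  fc <- filter$fc_hz
  p <- filter$p
  total <- 0
  for (i in seq_len(nrow(bands))) {
    f1 <- bands$f_lo_hz[i]
    f2 <- bands$f_hi_hz[i]
    if (f2 <= f1) abort("masker band has non-positive width")
    dens <- db_to_power(bands$density_db_hz[i])
    # split at fc; convert each sub-band to a g-interval on one skirt
    area <- 0
    if (f1 < fc) {
      hi <- min(f2, fc)
      area <- area + roex_band_integral(p, (fc - hi) / fc, (fc - f1) / fc)
    }
    if (f2 > fc) {
      lo <- max(f1, fc)
      area <- area + roex_band_integral(p, (lo - fc) / fc, (f2 - fc) / fc)
    }
    total <- total + dens * fc * area
  }
  if (total <= 0) abort("filtered masker power is zero")
  power_to_db(total)
}

#' Power-spectrum-model threshold for a masker geometry
#'
#' Predicted detection threshold of a tone at the filter's centre frequency:
#' `threshold = K + 10*log10(fc * sum_bands integral(W) * density)`, i.e. the
#' detector needs a fixed signal-to-filtered-masker ratio `K` (efficiency) at
#' the output of a single roex filter centred on the signal.
#'
#' @param filter A [roex_filter()].
#' @param bands Tibble of flat masker bands with columns `f_lo_hz`,
#'   `f_hi_hz`, `density_db_hz` (spectrum level, dB SPL per Hz).
#' @param efficiency_k_db Detector efficiency `K` (dB).
#' @param floor_db Optional absolute-threshold floor; predictions are clipped
#'   from below when supplied.
#' @return Predicted threshold (dB SPL).
#' @export
predict_notch_threshold <- function(filter, bands, efficiency_k_db,
                                    floor_db = NULL) {
  th <- efficiency_k_db + filtered_masker_power_db(filter, bands)
  if (!is.null(floor_db)) th <- max(th, floor_db)
  th
}

# Bands tibble for a notched-noise masker of overall level `level_db_spl`
# (both flanking bands together). Spectrum level is constant across notch
# widths because the total width in Hz is constant.
notch_masker_bands <- function(fc_hz, delta_f_frac, level_db_spl,
                               ref_width_oct = 1) {
  b <- notch_bands(fc_hz, delta_f_frac, ref_width_oct)
  total_bw <- sum(b$f_hi_hz - b$f_lo_hz)
  b$density_db_hz <- level_db_spl - power_to_db(total_bw)
  b
}

#' Signal-to-masker ratio at the output of an auditory filter
#'
#' Probe level minus the filtered masker power, for a probe at the filter's
#' centre frequency.
#'
#' @param probe_level_db Probe level (dB SPL).
#' @inheritParams predict_notch_threshold
#' @return SMR in dB.
#' @export
smr_at_filter_output <- function(probe_level_db, bands, filter) {
  probe_level_db - filtered_masker_power_db(filter, bands)
}

#' Fit a symmetric roex(p) filter to notched-noise thresholds
#'
#' Least-squares fit in dB space of the power-spectrum model
#' ([predict_notch_threshold()]) to thresholds measured at several notch
#' widths. The steepness `p` is profiled on a log grid and refined with
#' golden-section search (ties broken toward the smaller, broader-filter
#' `p`); the efficiency `K` is solved in closed form at each `p`. When the
#' data contain a `subject` column the default fits the mean threshold per
#' notch width.
#'
#' @param data Tibble with columns `delta_f_frac`, `threshold_db_spl` and
#'   optionally `subject`.
#' @param fc_hz Probe/centre frequency (Hz).
#' @param masker_level_db_spl Overall level of the (unnotched) masker band
#'   (dB SPL); the spectrum level follows from the constant total bandwidth.
#' @param ref_width_oct Width of the unnotched reference band (octaves).
#' @param floor_db Optional absolute-threshold floor applied to predictions.
#' @param p_range Search range for `p`.
#' @return A `roex_fit` object with elements `p_hat`, `erb_hat_hz`,
#'   `efficiency_k_db`, `fitted`, `data`, and fit diagnostics. Methods:
#'   [tidy()], [glance()], [autoplot()].
#' @examples
#' d <- sim_notch_thresholds(477, 4000, -3, noise_sd_db = 0, n_subjects = 1,
#'                           masker_level_db_spl = 67.9, seed = 1)
#' fit_roex(d, fc_hz = 4000, masker_level_db_spl = 67.9)
#' @export
fit_roex <- function(data, fc_hz, masker_level_db_spl,
                     ref_width_oct = 1, floor_db = NULL,
                     p_range = c(3, 300)) {
  stopifnot(is.data.frame(data))
  if (!all(c("delta_f_frac", "threshold_db_spl") %in% names(data))) {
    abort("`data` needs columns delta_f_frac and threshold_db_spl")
  }
  mean_th <- data %>%
    group_by(.data$delta_f_frac) %>%
    summarise(threshold_db_spl = mean(.data$threshold_db_spl), .groups = "drop")
  if (nrow(mean_th) < 3) {
    abort("need thresholds at >= 3 notch widths to fit p and K")
  }
  deltas <- mean_th$delta_f_frac
  th <- mean_th$threshold_db_spl

  geom <- lapply(deltas, function(d) {
    notch_masker_bands(fc_hz, d, masker_level_db_spl, ref_width_oct)
  })
  predict_at <- function(p) {
    filt <- roex_filter(fc_hz, p = p)
    vapply(geom, function(b) {
      filtered_masker_power_db(filt, b)
    }, numeric(1))
  }
  sse_at <- function(p) {
    x <- predict_at(p)
    k <- mean(th - x)
    pred <- k + x
    if (!is.null(floor_db)) pred <- pmax(pred, floor_db)
    sum((th - pred)^2)
  }
  grid <- exp(seq(log(p_range[1]), log(p_range[2]), length.out = 60))
  sse <- vapply(grid, sse_at, numeric(1))
  i <- which.min(sse) # which.min takes the first (smallest p) on ties
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(sse_at, lower = lo, upper = hi, tol = 1e-6)
  p_hat <- opt$minimum
  x <- predict_at(p_hat)
  k_hat <- mean(th - x)
  fitted <- k_hat + x
  if (!is.null(floor_db)) fitted <- pmax(fitted, floor_db)

  structure(
    list(
      p_hat = p_hat,
      erb_hat_hz = 4 * fc_hz / p_hat,
      efficiency_k_db = k_hat,
      fc_hz = fc_hz,
      masker_level_db_spl = masker_level_db_spl,
      ref_width_oct = ref_width_oct,
      floor_db = floor_db,
      data = mean_th,
      fitted = tibble(
        delta_f_frac = deltas,
        threshold_db_spl = th,
        fitted_db_spl = fitted
      ),
      sse = opt$objective,
      converged = is.finite(opt$objective) &&
        p_hat > p_range[1] * 1.0001 && p_hat < p_range[2] * 0.9999
    ),
    class = "roex_fit"
  )
}

#' @export
print.roex_fit <- function(x, ...) {
  cat(sprintf(
    "<roex_fit> fc = %g Hz: p = %.2f, ERB = %.0f Hz, K = %.1f dB (RMS resid %.2f dB)\n",
    x$fc_hz, x$p_hat, x$erb_hat_hz, x$efficiency_k_db,
    sqrt(x$sse / nrow(x$fitted))
  ))
  if (!x$converged) cat("  warning: fit at search-range boundary\n")
  invisible(x)
}

#' Bootstrap the fitted ERB over subjects
#'
#' Resamples subjects with replacement, refits the roex filter to the
#' resampled mean thresholds, and summarises the fitted ERB over bootstrap
#' samples. This matches cohort designs in which a single filter is fit to
#' group-mean thresholds and uncertainty is propagated from between-subject
#' variability.
#'
#' @param data Tibble with columns `subject`, `delta_f_frac`,
#'   `threshold_db_spl`.
#' @param n_boot Number of bootstrap samples (the reference analyses used
#'   10,000).
#' @param seed Integer seed (resampling is deterministic given the seed).
#' @inheritParams fit_roex
#' @return List with `erb_boot_mean_hz`, `erb_boot_sd_hz`, `n_boot`, `seed`
#'   and the vector of bootstrap ERBs (`erb_hz`).
#' @export
bootstrap_erb <- function(data, fc_hz, masker_level_db_spl, n_boot = 10000,
                          seed = 1, ref_width_oct = 1, floor_db = NULL) {
  if (!"subject" %in% names(data)) abort("`data` needs a `subject` column")
  subjects <- unique(data$subject)
  if (length(subjects) < 2) abort("need >= 2 subjects to bootstrap")
  wide <- data %>%
    group_by(.data$subject, .data$delta_f_frac) %>%
    summarise(threshold_db_spl = mean(.data$threshold_db_spl), .groups = "drop")
  erb <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      take <- sample(subjects, length(subjects), replace = TRUE)
      res <- bind_rows(lapply(take, function(s) wide[wide$subject == s, ]))
      fit_roex(res, fc_hz, masker_level_db_spl,
        ref_width_oct = ref_width_oct, floor_db = floor_db
      )$erb_hat_hz
    }, numeric(1))
  })
  list(
    erb_boot_mean_hz = mean(erb),
    erb_boot_sd_hz = sd(erb),
    n_boot = n_boot,
    seed = seed,
    erb_hz = erb
  )
}
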