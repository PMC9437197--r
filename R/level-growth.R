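#' Fit a shared-slope COR level-growth model
#'
#' Fits `COR_dB = x * level + subject terms` by least squares: one common
#' level slope `x` (dB of COR per dB of probe level) with a per-subject
#' intercept and, when several probe frequencies are present, a per-subject
#' `log10(frequency)` term. The 95% confidence interval for the slope is
#' obtained by resampling subjects with replacement and refitting.
#'
#' The shared slope is the quantity that converts COR masking into an
#' equivalent probe-level reduction (see [masking_to_threshold_shift()]);
#' reference values are about 0.16 dB/dB for human N1-P2 responses and 0.34
#' dB/dB for cat P1-N1 responses.
#'
#' @param data Tibble with columns `subject`, `level_db_spl`, `cor_db`
#'   (COR amplitude in dB re 1 uV) and optionally `freq_hz`.
#' @param n_boot Bootstrap resamples for the slope CI (0 skips the
#'   bootstrap and leaves the CI as `NA`).
#' @param seed Integer seed for the bootstrap.
#' @return A `growth_fit` object with `slope_db_per_db`, `ci95_slope`,
#'   per-subject coefficient tibble, and the underlying `lm` fit. Methods:
#'   [tidy()], [glance()], [autoplot()].
#' @export
fit_growth <- function(data, n_boot = 500, seed = 1) {
  stopifnot(is.data.frame(data))
  need <- c("subject", "level_db_spl", "cor_db")
  if (!all(need %in% names(data))) {
    abort("`data` needs columns subject, level_db_spl, cor_db")
  }
  counts <- data %>% count(.data$subject)
  n_levels <- data %>%
    group_by(.data$subject) %>%
    summarise(k = length(unique(.data$level_db_spl)), .groups = "drop")
  if (any(n_levels$k < 3)) {
    abort("every subject needs >= 3 probe levels")
  }
  data <- data %>% mutate(subject = factor(.data$subject))
  has_freq <- "freq_hz" %in% names(data) &&
    length(unique(data$freq_hz)) > 1
  fml <- if (has_freq) {
    cor_db ~ 0 + level_db_spl + subject + subject:log10(freq_hz)
  } else {
    cor_db ~ 0 + level_db_spl + subject
  }
  fit <- lm(fml, data = data)
  slope <- unname(coef(fit)["level_db_spl"])

  subjects <- levels(data$subject)
  boot_slopes <- if (n_boot < 1) numeric(0) else withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      take <- sample(subjects, length(subjects), replace = TRUE)
      res <- bind_rows(lapply(seq_along(take), function(i) {
        d <- data[data$subject == take[i], ]
        d$subject <- paste0("bs", i) # resampled copies are distinct subjects
        d
      }))
      res$subject <- factor(res$subject)
      unname(coef(lm(fml, data = res))["level_db_spl"])
    }, numeric(1))
  })
  ci <- if (n_boot < 1) c(NA_real_, NA_real_) else {
    unname(quantile(boot_slopes, c(0.025, 0.975)))
  }

  structure(
    list(
      slope_db_per_db = slope,
      ci95_slope = ci,
      boot_slopes = boot_slopes,
      n_boot = n_boot,
      seed = seed,
      has_freq_term = has_freq,
      coefficients = tibble(
        term = names(coef(fit)), estimate = unname(coef(fit))
      ),
      level_range_db = range(data$level_db_spl),
      fit = fit,
      data = data
    ),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "<growth_fit> slope = %.3f dB/dB (95%% CI %.3f-%.3f, %d subject resamples)\n",
    x$slope_db_per_db, x$ci95_slope[1], x$ci95_slope[2], x$n_boot
  ))
  invisible(x)
}

#' Convert COR masking to an equivalent threshold shift
#'
#' Divides the masker-induced COR reduction (in dB re the unmasked
#' response) by the level-growth slope, giving the reduction in probe level
#' in quiet that would produce the same COR reduction — an estimate of the
#' psychophysical threshold shift on the stimulus-level axis.
#'
#' @param cor_masking_db COR masking, dB re unmasked (non-positive values
#'   expected; the magnitude is used).
#' @param slope_db_per_db Level-growth slope (> 0), e.g. 0.16 (human) or a
#'   [fit_growth()] result's `slope_db_per_db`.
#' @return Estimated threshold shift (dB, >= 0), linear in the masking.
#' @examples
#' masking_to_threshold_shift(-1.6, 0.16) # 10 dB
#' @export
masking_to_threshold_shift <- function(cor_masking_db, slope_db_per_db) {
  if (any(!is.finite(slope_db_per_db)) || any(slope_db_per_db <= 0)) {
    abort("`slope_db_per_db` must be positive")
  }
  abs(cor_masking_db) / slope_db_per_db
}

#' Compare COR-estimated and psychophysical threshold shifts
#'
#' Joins COR masking (converted to threshold shifts at one or more growth
#' slopes) with measured psychophysical threshold elevations on a shared
#' frequency grid, and reports the per-frequency discrepancy. Sweeping the
#' slope over its confidence limits (e.g. 0.13, 0.16, 0.19 dB/dB) shows the
#' sensitivity of the comparison; halving the slope exactly doubles every
#' estimated shift.
#'
#' @param psycho Tibble with `freq_hz`, `shift_db` (measured threshold
#'   elevation re quiet).
#' @param cor Tibble with `freq_hz`, `cor_masking_db` (dB re unmasked).
#' @param slopes Growth slopes (dB/dB) to sweep.
#' @return Tibble with one row per frequency x slope: `freq_hz`,
#'   `slope_db_per_db`, `psycho_shift_db`, `cor_shift_db`, `discrepancy_db`
#'   (COR estimate minus psychophysics).
#' @export
compare_shift_estimates <- function(psycho, cor,
                                    slopes = c(0.13, 0.16, 0.19)) {
  stopifnot(is.data.frame(psycho), is.data.frame(cor))
  if (!setequal(psycho$freq_hz, cor$freq_hz) ||
      nrow(psycho) != nrow(cor)) {
    abort("`psycho` and `cor` must share the same frequency grid")
  }
  joined <- left_join(
    rename(psycho, psycho_shift_db = "shift_db"),
    cor,
    by = "freq_hz"
  )
  bind_rows(lapply(slopes, function(s) {
    joined %>%
      mutate(
        slope_db_per_db = s,
        cor_shift_db = masking_to_threshold_shift(.data$cor_masking_db, s),
        discrepancy_db = .data$cor_shift_db - .data$psycho_shift_db
      ) %>%
      select(
        "freq_hz", "slope_db_per_db", "psycho_shift_db",
        "cor_shift_db", "discrepancy_db"
      )
  }))
}
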