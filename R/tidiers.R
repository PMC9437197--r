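# broom-style tidy()/glance() methods for the fitted objects

#' @describeIn fit_roex One row per notch width with observed and fitted
#'   thresholds.
#' @param x A `roex_fit`.
#' @param ... Unused.
#' @export
tidy.roex_fit <- function(x, ...) x$fitted

#' @describeIn fit_roex One-row model summary: `p`, `erb_hz`,
#'   `efficiency_k_db`, `rms_resid_db`, `n`, `converged`.
#' @export
glance.roex_fit <- function(x, ...) {
  tibble(
    p = x$p_hat,
    erb_hz = x$erb_hat_hz,
    efficiency_k_db = x$efficiency_k_db,
    rms_resid_db = sqrt(x$sse / nrow(x$fitted)),
    n = nrow(x$fitted),
    converged = x$converged
  )
}

#' @describeIn fit_growth Model coefficients (shared slope and per-subject
#'   terms).
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @export
tidy.growth_fit <- function(x, ...) x$coefficients

#' @describeIn fit_growth One-row summary: slope, bootstrap CI, subject and
#'   observation counts.
#' @export
glance.growth_fit <- function(x, ...) {
  tibble(
    slope_db_per_db = x$slope_db_per_db,
    ci95_lo = x$ci95_slope[1],
    ci95_hi = x$ci95_slope[2],
    n_subjects = length(unique(x$data$subject)),
    n_obs = nrow(x$data),
    has_freq_term = x$has_freq_term
  )
}

#' @describeIn fit_threshold_pcmax Data with fitted P(c)max values.
#' @param x A `pcmax_fit`.
#' @param ... Unused.
#' @export
tidy.pcmax_fit <- function(x, ...) {
  x$data %>% mutate(fitted = predict(x, .data$probe_level_db))
}

#' @describeIn fit_threshold_pcmax One-row summary: threshold, criterion,
#'   logistic parameters, flags.
#' @export
glance.pcmax_fit <- function(x, ...) {
  tibble(
    threshold_db = x$threshold_db,
    criterion = x$criterion,
    midpoint_db = x$midpoint_db,
    slope_db = x$slope_db,
    extrapolated = x$extrapolated,
    increasing = x$increasing,
    converged = x$converged
  )
}
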