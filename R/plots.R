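# ggplot2 autoplot methods

#' @describeIn sampled_signal Periodogram of the signal (dB re max).
#' @param object A `sampled_signal`.
#' @param ... Unused.
#' @export
autoplot.sampled_signal <- function(object, ...) {
  x <- object$samples
  n <- length(x)
  spec <- Mod(fft(x))[1:(n %/% 2)]^2
  df <- tibble(
    freq_hz = (0:(n %/% 2 - 1)) * object$rate_hz / n,
    power_db = power_to_db(pmax(spec / max(spec), 1e-12))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$freq_hz, .data$power_db)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Frequency (Hz)", y = "Power (dB re max)",
      title = "Signal spectrum"
    )
}

#' @describeIn average_epochs Averaged waveform with the configured peak
#'   windows shaded.
#' @param object A `cor_average`.
#' @param ... Unused.
#' @export
autoplot.cor_average <- function(object, ...) {
  df <- tibble(time_ms = object$times_ms, amplitude_uv = object$waveform)
  windows <- bind_rows(lapply(
    names(object$config$peak_windows_ms),
    function(p) {
      w <- object$config$peak_windows_ms[[p]]
      tibble(peak = p, from = w[1], to = w[2])
    }
  ))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$amplitude_uv)) +
    ggplot2::geom_rect(
      data = windows,
      ggplot2::aes(
        xmin = .data$from, xmax = .data$to,
        ymin = -Inf, ymax = Inf, fill = .data$peak
      ),
      alpha = 0.15, inherit.aes = FALSE
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "Time re probe onset (ms)", y = "Amplitude (uV)",
      title = sprintf("Averaged onset response (n = %d epochs)",
                      object$n_epochs_used)
    )
}

#' @describeIn fit_roex Thresholds versus notch width with the fitted
#'   power-spectrum-model curve.
#' @param object A `roex_fit`.
#' @export
autoplot.roex_fit <- function(object, ...) {
  grid <- tibble(delta_f_frac = seq(0, max(object$fitted$delta_f_frac),
                                    length.out = 50))
  filt <- roex_filter(object$fc_hz, p = object$p_hat)
  grid$fitted_db_spl <- vapply(grid$delta_f_frac, function(d) {
    predict_notch_threshold(
      filt,
      notch_masker_bands(object$fc_hz, d, object$masker_level_db_spl,
                         object$ref_width_oct),
      object$efficiency_k_db, floor_db = object$floor_db
    )
  }, numeric(1))
  ggplot2::ggplot(object$fitted,
                  ggplot2::aes(.data$delta_f_frac, .data$threshold_db_spl)) +
    ggplot2::geom_line(
      data = grid, ggplot2::aes(y = .data$fitted_db_spl),
      colour = "grey40"
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = expression(paste(Delta, "f (fraction of centre frequency)")),
      y = "Threshold (dB SPL)",
      title = sprintf("roex(p) fit: ERB = %.0f Hz", object$erb_hat_hz)
    )
}

#' @describeIn fit_threshold_pcmax P(c)max versus level with the fitted
#'   logistic and the threshold criterion.
#' @param object A `pcmax_fit`.
#' @export
autoplot.pcmax_fit <- function(object, ...) {
  lev <- object$data$probe_level_db
  grid <- tibble(probe_level_db = seq(min(lev) - 2, max(lev) + 2,
                                      length.out = 100))
  grid$pcmax <- predict(object, grid$probe_level_db)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$probe_level_db, .data$pcmax)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = object$criterion, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = object$threshold_db,
                        linetype = "dotted") +
    ggplot2::labs(
      x = "Probe level (dB SPL)", y = "P(c)max",
      title = sprintf("Threshold %.1f dB at P(c)max = %.2f",
                      object$threshold_db, object$criterion)
    )
}

#' @describeIn excitation Excitation pattern across the channel array.
#' @param object An `excitation_pattern`.
#' @export
autoplot.excitation_pattern <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$fc_hz, .data$level_db)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Channel centre frequency (Hz)", y = "Channel output (dB SPL)",
      title = "Excitation pattern"
    )
}

#' @describeIn fit_growth COR amplitude versus probe level per subject with
#'   the shared-slope fit.
#' @param object A `growth_fit`.
#' @export
autoplot.growth_fit <- function(object, ...) {
  df <- object$data %>% mutate(fitted = stats::fitted(object$fit))
  ggplot2::ggplot(df, ggplot2::aes(.data$level_db_spl, .data$cor_db,
                                   colour = .data$subject)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::labs(
      x = "Probe level (dB SPL)", y = "COR (dB re 1 uV)",
      title = sprintf("Level growth: shared slope %.2f dB/dB",
                      object$slope_db_per_db)
    )
}
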