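#' Score hold-release pedal latencies
#'
#' Scores release latencies relative to probe onset with the hold-release
#' convention: releases earlier than 1000 ms before probe onset are
#' `"early"` (not scored further), releases in `[-1000, 0)` ms are
#' `"false_alarm"`, releases in `[0, 1000]` ms are `"hit"`, and later or
#' absent releases are `"miss"`. The half-open boundaries make the four
#' categories an exact partition.
#'
#' @param release_ms_re_probe Release latency in ms re probe onset; `NA`
#'   means the pedal was never released (miss).
#' @return Character vector with values `"early"`, `"false_alarm"`, `"hit"`,
#'   `"miss"`.
#' @examples
#' score_release(c(-1200, -500, 400, 1500, NA))
#' @export
score_release <- function(release_ms_re_probe) {
  r <- release_ms_re_probe
  out <- rep("miss", length(r))
  out[!is.na(r) & r < -1000] <- "early"
  out[!is.na(r) & r >= -1000 & r < 0] <- "false_alarm"
  out[!is.na(r) & r >= 0 & r <= 1000] <- "hit"
  out
}

#' Score a table of hold-release trials
#'
#' @param trials Tibble with at least `hold_s` and `release_ms_re_probe`.
#' @return The input with a `score` column added (see [score_release()]).
#' @export
score_trials <- function(trials) {
  stopifnot(is.data.frame(trials))
  trials %>% mutate(score = score_release(.data$release_ms_re_probe))
}

# Per-hold counts and rates over scored (non-early) trials.
hold_rates <- function(trials) {
  if (!"score" %in% names(trials)) trials <- score_trials(trials)
  trials %>%
    filter(.data$score != "early") %>%
    group_by(hold_s = .data$hold_s) %>%
    summarise(
      n_scored = n(),
      n_fa = sum(.data$score == "false_alarm"),
      n_hit = sum(.data$score == "hit"),
      n_miss = sum(.data$score == "miss"),
      .groups = "drop"
    ) %>%
    mutate(
      p_fa = .data$n_fa / .data$n_scored,
      p_hit = ifelse(.data$n_hit + .data$n_miss > 0,
        .data$n_hit / (.data$n_hit + .data$n_miss), NA_real_
      )
    )
}

#' Weighted false-alarm rate from catch-trial holds
#'
#' In the hold-release paradigm the false-alarm window of Hold N+1 trials
#' coincides exactly with the hit window of Hold N trials, so the false
#' alarms on Holds 3, 4 and 5 serve as catch trials for Holds 2, 3 and 4.
#' The per-hold false-alarm rates (Holds 3-5) are averaged with weights
#' given by the distribution of tested Holds 2-4 in `trials`.
#'
#' @param trials Scored or unscored trial tibble (see [score_trials()]); all
#'   trials passed in are pooled, so group beforehand (e.g. by masker
#'   condition) as required.
#' @param weights Optional named numeric vector of weights for holds 2, 3, 4
#'   (names `"2"`, `"3"`, `"4"`); defaults to the observed distribution of
#'   scored trials at those holds.
#' @return Weighted false-alarm rate (proportion, unclipped).
#' @export
weighted_false_alarm_rate <- function(trials, weights = NULL) {
  rates <- hold_rates(trials)
  fa <- setNames(rates$p_fa, rates$hold_s)
  need <- as.character(3:5)
  if (!all(need %in% names(fa))) {
    abort("trials must include holds 3, 4 and 5 for catch-trial rates")
  }
  if (is.null(weights)) {
    w <- setNames(rates$n_scored, rates$hold_s)[as.character(2:4)]
    w[is.na(w)] <- 0
  } else {
    w <- weights[as.character(2:4)]
  }
  if (sum(w) <= 0) abort("no tested trials at holds 2-4 to weight by")
  w <- w / sum(w)
  # FA rate of hold h+1 is the catch rate for tested hold h
  sum(w * fa[need])
}

#' d-prime and unbiased proportion correct
#'
#' Equal-variance Gaussian signal-detection statistics for a yes/no (go,
#' no-go) task: `d' = z(P_hit) - z(P_fa)` and the bias-free maximum
#' proportion correct `P(c)max = Phi(d'/2)`. `d' = 1` corresponds to
#' `P(c)max = 0.69`, the threshold criterion used throughout.
#'
#' Proportions of exactly 0 or 1 are replaced by `1/(2N)` and `1 - 1/(2N)`
#' when trial counts are supplied; otherwise they are rejected.
#'
#' @param p_hit,p_fa Hit and false-alarm proportions.
#' @param n_hit,n_fa Optional trial counts behind each proportion, used for
#'   the 1/(2N) clipping rule.
#' @return Tibble with `p_hit`, `p_fa`, `d_prime`, `pcmax`.
#' @examples
#' detection_stats(pnorm(0.5), pnorm(-0.5)) # d' = 1, P(c)max = 0.69
#' @export
detection_stats <- function(p_hit, p_fa, n_hit = NULL, n_fa = NULL) {
  clip <- function(p, n, name) {
    bad <- p <= 0 | p >= 1
    if (any(bad)) {
      if (is.null(n)) {
        abort(paste0("`", name, "` at 0 or 1 requires trial counts to clip"))
      }
      p <- pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
    }
    p
  }
  p_hit <- clip(p_hit, n_hit, "p_hit")
  p_fa <- clip(p_fa, n_fa, "p_fa")
  d <- qnorm(p_hit) - qnorm(p_fa)
  tibble(p_hit = p_hit, p_fa = p_fa, d_prime = d, pcmax = pnorm(d / 2))
}

#' Level-by-level P(c)max from a hold-release session
#'
#' Computes, per probe level, the hit rate over probe-bearing scored trials
#' (Holds 2-4; Hold-5 trials serve only as catch trials) against the
#' session-wide weighted false-alarm rate ([weighted_false_alarm_rate()]),
#' and converts to d-prime and P(c)max.
#'
#' @param trials Trial tibble with `hold_s`, `release_ms_re_probe`,
#'   `probe_level_db` (pool or pre-group by masker/frequency as needed).
#' @return A tibble with one row per probe level: `probe_level_db`,
#'   `n_trials`, `p_hit`, `p_fa`, `d_prime`, `pcmax`.
#' @export
psychometric_points <- function(trials) {
  trials <- score_trials(trials)
  p_fa <- weighted_false_alarm_rate(trials)
  n_fa_eff <- sum(hold_rates(trials)$n_scored)
  trials %>%
    filter(.data$score %in% c("hit", "miss"), .data$hold_s < 5) %>%
    group_by(probe_level_db = .data$probe_level_db) %>%
    summarise(
      n_trials = n(),
      n_hit = sum(.data$score == "hit"),
      .groups = "drop"
    ) %>%
    mutate(
      stats = purrr::map2(
        .data$n_hit / .data$n_trials, .data$n_trials,
        function(ph, n) {
          detection_stats(ph, p_fa, n_hit = n, n_fa = n_fa_eff)
        }
      )
    ) %>%
    tidyr::unnest("stats") %>%
    select("probe_level_db", "n_trials", "p_hit", "p_fa", "d_prime", "pcmax")
}

# Fast base-R pooled P(c)max for one assignment of releases to holds; used
# both for the observed session statistic and inside the permutation loop
# (where dplyr verbs would dominate the run time). Semantics identical to
# weighted_false_alarm_rate() + detection_stats(): per-hold FA rates for
# holds 3-5 weighted by the tested distribution of holds 2-4, hit rate over
# probe-bearing (hit/miss, holds 2-4) trials, 1/(2N) clipping.
fast_session_pcmax <- function(hold_s, release_ms) {
  sc <- score_release(release_ms)
  scored <- sc != "early"
  h <- hold_s[scored]
  s <- sc[scored]
  n_scored <- vapply(2:5, function(k) sum(h == k), numeric(1))
  n_fa <- vapply(2:5, function(k) sum(h == k & s == "false_alarm"), numeric(1))
  w <- n_scored[1:3] # holds 2-4
  if (sum(w) <= 0) abort("no tested trials at holds 2-4 to weight by")
  w <- w / sum(w)
  fa_rate <- ifelse(n_scored[2:4] > 0, n_fa[2:4] / n_scored[2:4], 0)
  p_fa <- sum(w * fa_rate)
  probe <- h < 5 & s %in% c("hit", "miss")
  n <- sum(probe)
  if (n == 0) abort("no probe-bearing scored trials")
  p_hit <- sum(s[probe] == "hit") / n
  n_fa_eff <- sum(n_scored)
  clip <- function(p, nn) pmin(pmax(p, 1 / (2 * nn)), 1 - 1 / (2 * nn))
  pnorm((qnorm(clip(p_hit, n)) - qnorm(clip(p_fa, n_fa_eff))) / 2)
}

# Single pooled P(c)max for a session (all probe levels combined); the
# statistic permuted by permutation_chance().
session_pcmax <- function(trials) {
  fast_session_pcmax(trials$hold_s, trials$release_ms_re_probe)
}

#' Logistic threshold at a P(c)max criterion
#'
#' Fits a logistic function with lower asymptote fixed at chance (0.5) to
#' P(c)max versus probe level by (optionally trial-weighted) least squares,
#' and returns the interpolated level at which the curve crosses the
#' criterion (0.69, corresponding to d' = 1, by default).
#'
#' @param data Tibble with `probe_level_db`, `pcmax` and optionally
#'   `n_trials` (used as weights).
#' @param criterion P(c)max criterion for threshold (default 0.69).
#' @param upper Upper asymptote (fixed, default 1).
#' @return A `pcmax_fit` object with `threshold_db`, `midpoint_db`,
#'   `slope_db`, `extrapolated` flag and the data/fitted values. Methods:
#'   [tidy()], [glance()], [autoplot()].
#' @export
fit_threshold_pcmax <- function(data, criterion = 0.69, upper = 1) {
  stopifnot(is.data.frame(data))
  if (!all(c("probe_level_db", "pcmax") %in% names(data))) {
    abort("`data` needs columns probe_level_db and pcmax")
  }
  if (criterion <= 0.5 || criterion >= upper) {
    abort("`criterion` must lie between 0.5 and `upper`")
  }
  lev <- data$probe_level_db
  pc <- data$pcmax
  w <- if ("n_trials" %in% names(data)) data$n_trials else rep(1, length(pc))
  if (length(unique(lev)) < 3) abort("need >= 3 probe levels")

  fn <- function(par) {
    mid <- par[1]
    slope <- exp(par[2]) # dB width parameter, kept positive
    pred <- 0.5 + (upper - 0.5) / (1 + exp(-(lev - mid) / slope))
    sum(w * (pc - pred)^2)
  }
  start <- c(mean(range(lev)), log(max(2, diff(range(lev)) / 4)))
  opt <- optim(start, fn, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  mid <- opt$par[1]
  slope <- exp(opt$par[2])
  # invert: criterion = 0.5 + (upper-.5)/(1+exp(-(L-mid)/slope))
  q <- (criterion - 0.5) / (upper - 0.5)
  threshold <- mid + slope * log(q / (1 - q))

  # a fit is only an interpolation if the data bracket the criterion
  extrapolated <- max(pc) < criterion || min(pc) > criterion ||
    threshold < min(lev) || threshold > max(lev)
  increasing <- stats::cor(lev, pc) > 0
  if (!increasing) {
    warn("P(c)max decreases with level; threshold flagged as unreliable")
  }
  structure(
    list(
      threshold_db = threshold,
      criterion = criterion,
      midpoint_db = mid,
      slope_db = slope,
      upper = upper,
      extrapolated = extrapolated,
      increasing = increasing,
      sse = opt$value,
      data = tibble(probe_level_db = lev, pcmax = pc, weight = w),
      converged = opt$convergence == 0
    ),
    class = "pcmax_fit"
  )
}

#' @export
print.pcmax_fit <- function(x, ...) {
  cat(sprintf(
    "<pcmax_fit> threshold = %.1f dB at P(c)max = %.2f (midpoint %.1f dB, slope %.1f dB)%s\n",
    x$threshold_db, x$criterion, x$midpoint_db, x$slope_db,
    if (x$extrapolated) " [extrapolated]" else ""
  ))
  invisible(x)
}

#' Predicted P(c)max from a pcmax_fit
#'
#' @param object A `pcmax_fit`.
#' @param level_db Probe levels at which to evaluate the fitted logistic.
#' @param ... Unused.
#' @return Numeric vector of P(c)max values.
#' @export
predict.pcmax_fit <- function(object, level_db, ...) {
  0.5 + (object$upper - 0.5) /
    (1 + exp(-(level_db - object$midpoint_db) / object$slope_db))
}

#' Permutation ceiling for chance P(c)max
#'
#' Estimates the chance distribution of the pooled session P(c)max by
#' breaking the association between hold times and pedal releases: release
#' times are re-expressed on the masker-onset timebase, shuffled across
#' trials (hold labels kept), rescored and re-summarised. Returns the stated
#' percentile of the permuted P(c)max values; an observed P(c)max above this
#' ceiling indicates above-chance detection.
#'
#' @param trials Trial tibble (`hold_s`, `release_ms_re_probe`, ...).
#' @param n_perm Number of permutations (>= 1000 recommended).
#' @param seed Integer seed; the ceiling is deterministic given the seed.
#' @param percentile Percentile of the chance distribution (default 95).
#' @return List with `ceiling` (the percentile), `observed` (the session's
#'   actual pooled P(c)max), `pcmax_perm` (all permuted values), `n_perm`,
#'   `percentile`, `seed`.
#' @export
permutation_chance <- function(trials, n_perm = 1000, seed = 1,
                               percentile = 95) {
  stopifnot(is.data.frame(trials))
  if (nrow(trials) < 10) abort("too few trials to permute")
  observed <- session_pcmax(trials)
  release_abs_ms <- trials$release_ms_re_probe + trials$hold_s * 1000
  hold_ms <- trials$hold_s * 1000
  pcmax_perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      shuffled <- sample(release_abs_ms)
      fast_session_pcmax(trials$hold_s, shuffled - hold_ms)
    }, numeric(1))
  })
  list(
    ceiling = unname(quantile(pcmax_perm, percentile / 100)),
    observed = observed,
    pcmax_perm = pcmax_perm,
    n_perm = n_perm,
    percentile = percentile,
    seed = seed
  )
}
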