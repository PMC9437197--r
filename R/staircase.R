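#' Two-alternative forced-choice logistic observer
#'
#' Percent-correct psychometric function of a simulated 2AFC observer whose
#' detection probability is logistic in probe level:
#' `P(correct) = 0.5 + 0.5 * (1 - lapse) / (1 + exp(-(L - midpoint)/slope))`.
#'
#' @param level_db Probe level(s), dB.
#' @param midpoint_db Level of the detection-function midpoint (dB).
#' @param slope_db Logistic width parameter (dB); smaller is steeper.
#' @param lapse Lapse rate (proportion of detections missed regardless of
#'   level).
#' @return Probability correct in \[0.5, 1\].
#' @export
psychometric_2afc <- function(level_db, midpoint_db, slope_db, lapse = 0) {
  p_detect <- (1 - lapse) / (1 + exp(-(level_db - midpoint_db) / slope_db))
  0.5 + 0.5 * p_detect
}

#' Run one 2-down 1-up adaptive staircase
#'
#' Transformed up-down track converging on the 70.7%-correct point of the
#' psychometric function: the level is increased after every incorrect
#' response and decreased after every two consecutive correct responses
#' (the correct counter resets on every level change). The step size is
#' `step_initial_db` (6 dB) until 2 turnpoints have occurred and
#' `step_final_db` (2 dB) thereafter; the run ends after `n_turnpoints` (8)
#' turnpoints and the threshold is the mean of the last
#' `n_turnpoints_mean` (6) turnpoint levels.
#'
#' @param p_correct Function of level (dB) returning the probability of a
#'   correct response (e.g. a closure over [psychometric_2afc()]), or a
#'   deterministic 0/1 responder for testing.
#' @param start_level_db Starting probe level (dB).
#' @param step_initial_db,step_final_db Step sizes (dB).
#' @param n_switch Turnpoint count after which the step size shrinks.
#' @param n_turnpoints Total turnpoints to collect.
#' @param n_turnpoints_mean How many final turnpoints enter the threshold.
#' @param max_trials Guard against non-terminating runs.
#' @return List with `threshold_db`, `turnpoints_db`, and a `track` tibble
#'   (`trial`, `level_db`, `correct`).
#' @export
run_staircase <- function(p_correct, start_level_db,
                          step_initial_db = 6, step_final_db = 2,
                          n_switch = 2, n_turnpoints = 8,
                          n_turnpoints_mean = 6, max_trials = 1000) {
  level <- start_level_db
  n_correct <- 0
  turn <- numeric(0)
  last_dir <- 0L # direction of the previous level change
  levels <- numeric(0)
  corrects <- logical(0)
  trial <- 0L
  while (length(turn) < n_turnpoints && trial < max_trials) {
    trial <- trial + 1L
    correct <- runif(1) < p_correct(level)
    levels[trial] <- level
    corrects[trial] <- correct
    move <- 0L
    if (!correct) {
      move <- +1L
      n_correct <- 0
    } else {
      n_correct <- n_correct + 1
      if (n_correct == 2) {
        move <- -1L
        n_correct <- 0
      }
    }
    if (move != 0L) {
      if (last_dir != 0L && move != last_dir) turn <- c(turn, level)
      step <- if (length(turn) < n_switch) step_initial_db else step_final_db
      level <- level + move * step
      last_dir <- move
    }
  }
  if (length(turn) < n_turnpoints) {
    warn("staircase hit max_trials before collecting all turnpoints")
  }
  used <- utils::tail(turn, n_turnpoints_mean)
  list(
    threshold_db = mean(used),
    turnpoints_db = turn,
    track = tibble(
      trial = seq_along(levels), level_db = levels, correct = corrects
    )
  )
}

#' Threshold from a session of staircase runs
#'
#' Runs two staircases and averages their thresholds; a third run is added
#' if the first two differ by more than 5 dB.
#'
#' @inheritParams run_staircase
#' @param max_diff_db Difference between the first two runs that triggers a
#'   third (default 5 dB).
#' @return List with `threshold_db`, `run_thresholds_db` and `n_runs`.
#' @export
run_staircase_session <- function(p_correct, start_level_db,
                                  max_diff_db = 5, ...) {
  t1 <- run_staircase(p_correct, start_level_db, ...)$threshold_db
  t2 <- run_staircase(p_correct, start_level_db, ...)$threshold_db
  runs <- c(t1, t2)
  if (abs(t1 - t2) > max_diff_db) {
    runs <- c(runs, run_staircase(p_correct, start_level_db, ...)$threshold_db)
  }
  list(
    threshold_db = mean(runs),
    run_thresholds_db = runs,
    n_runs = length(runs)
  )
}

#' Simulate many staircase runs against a logistic observer
#'
#' Convergence check for the 2-down 1-up rule: simulates independent runs on
#' a known logistic 2AFC observer and reports the distribution of converged
#' thresholds together with the percent correct the observer would score at
#' the mean threshold (nominally 70.7%).
#'
#' @param n_runs Number of independent staircase runs.
#' @param midpoint_db,slope_db,lapse Observer parameters
#'   ([psychometric_2afc()]).
#' @param start_level_db Starting level for every run.
#' @param seed Integer seed.
#' @param ... Passed to [run_staircase()].
#' @return List with `thresholds_db` (vector), `mean_threshold_db`, and
#'   `percent_correct_at_mean` (the observer's percent correct at the mean
#'   converged level).
#' @export
simulate_staircases <- function(n_runs, midpoint_db, slope_db, lapse = 0,
                                start_level_db = midpoint_db + 15, seed = 1,
                                ...) {
  fn <- function(level) psychometric_2afc(level, midpoint_db, slope_db, lapse)
  th <- withr::with_seed(seed, {
    vapply(seq_len(n_runs), function(i) {
      run_staircase(fn, start_level_db, ...)$threshold_db
    }, numeric(1))
  })
  m <- mean(th)
  list(
    thresholds_db = th,
    mean_threshold_db = m,
    percent_correct_at_mean = 100 * psychometric_2afc(
      m, midpoint_db, slope_db, lapse
    )
  )
}
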