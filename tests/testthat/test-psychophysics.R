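# Hold-release scoring, SDT statistics, thresholds, permutation test.

test_that("release scoring partitions every trial exactly once", {
  expect_equal(
    score_release(c(-1200, -500, 400, 1500, NA)),
    c("early", "false_alarm", "hit", "miss", "miss")
  )
  # boundary conventions: [-1000, 0) FA, [0, 1000] hit
  expect_equal(score_release(0), "hit")
  expect_equal(score_release(-1000), "false_alarm")
  expect_equal(score_release(1000), "hit")
  expect_equal(score_release(-1000.5), "early")
  expect_equal(score_release(1000.5), "miss")
  # partition property over random latencies
  r <- withr::with_seed(5, runif(500, -4000, 4000))
  s <- score_release(r)
  expect_equal(length(s), 500)
  expect_true(all(s %in% c("early", "false_alarm", "hit", "miss")))
  tr <- score_trials(tibble::tibble(hold_s = 3, release_ms_re_probe = r))
  expect_equal(sum(table(tr$score)), 500)
})

test_that("weighted false-alarm rate uses hold N+1 as catch for hold N", {
  mk <- function(h, n, nfa) {
    tibble::tibble(
      hold_s = h,
      release_ms_re_probe = c(rep(-500, nfa), rep(NA, n - nfa))
    )
  }
  # equal per-hold rates collapse to that rate for any weights
  eq <- dplyr::bind_rows(mk(3, 10, 2), mk(4, 10, 2), mk(5, 10, 2))
  expect_equal(
    weighted_false_alarm_rate(eq, weights = c("2" = .7, "3" = .2, "4" = .1)),
    0.2
  )
  # hand-computed weighted mean: rates (.1,.2,.3), weights (.5,.3,.2) -> .17
  tr <- dplyr::bind_rows(mk(3, 10, 1), mk(4, 10, 2), mk(5, 10, 3))
  expect_equal(
    weighted_false_alarm_rate(tr, weights = c("2" = .5, "3" = .3, "4" = .2)),
    0.17
  )
  # zero false alarms give zero before clipping
  z <- dplyr::bind_rows(mk(3, 10, 0), mk(4, 10, 0), mk(5, 10, 0))
  expect_equal(
    weighted_false_alarm_rate(z, weights = c("2" = 1, "3" = 0, "4" = 0)), 0
  )
  expect_error(weighted_false_alarm_rate(mk(3, 10, 1)), "holds 3, 4 and 5")
})

test_that("d-prime and P(c)max follow the equal-variance Gaussian model", {
  s <- detection_stats(pnorm(0.5), pnorm(-0.5))
  expect_equal(s$d_prime, 1, tolerance = 1e-10)
  expect_equal(round(s$pcmax, 2), 0.69)
  expect_equal(detection_stats(0.3, 0.3)$d_prime, 0)
  expect_equal(detection_stats(0.3, 0.3)$pcmax, 0.5)
  expect_equal(detection_stats(0.84, 0.5)$d_prime, qnorm(0.84),
    tolerance = 1e-10
  )
  # 1/(2N) clipping of extreme proportions
  c1 <- detection_stats(1, 0.2, n_hit = 20)
  expect_equal(c1$p_hit, 1 - 1 / 40)
  expect_error(detection_stats(1, 0.2), "requires trial counts")
})

test_that("d-prime is invariant to the observer's criterion", {
  # equal-variance Gaussian observer at d' = 1.4, criteria swept
  d <- 1.4
  for (crit in seq(-1, 1, by = 0.25)) {
    s <- detection_stats(pnorm(d / 2 - crit), pnorm(-d / 2 - crit))
    expect_equal(s$d_prime, d, tolerance = 1e-9)
    expect_equal(s$pcmax, pnorm(d / 2), tolerance = 1e-9)
  }
})

test_that("logistic threshold interpolation recovers known observers", {
  lv <- seq(30, 50, 2)
  true_mid <- 40
  pc <- 0.5 + 0.5 / (1 + exp(-(lv - true_mid) / 2.5))
  fit <- fit_threshold_pcmax(tibble::tibble(probe_level_db = lv, pcmax = pc))
  truth <- true_mid + 2.5 * log(0.38 / 0.62)
  expect_equal(fit$threshold_db, truth, tolerance = 0.5)
  expect_false(fit$extrapolated)
  expect_equal(predict(fit, fit$threshold_db), 0.69, tolerance = 1e-3)
  expect_equal(nrow(tidy(fit)), length(lv))
  expect_equal(glance(fit)$threshold_db, fit$threshold_db)

  # binomially sampled psychometric data: median error under 2 dB
  errs <- withr::with_seed(21, {
    replicate(150, {
      n <- sample(15:30, length(lv), replace = TRUE)
      obs <- rbinom(length(lv), n, pc) / n
      f <- fit_threshold_pcmax(
        tibble::tibble(probe_level_db = lv, pcmax = obs, n_trials = n)
      )
      abs(f$threshold_db - truth)
    })
  })
  expect_lt(median(errs), 2)

  # monotone-decreasing data are flagged
  expect_warning(
    bad <- fit_threshold_pcmax(
      tibble::tibble(probe_level_db = lv, pcmax = rev(pc))
    ),
    "unreliable"
  )
  expect_false(bad$increasing)
})

test_that("psychometric points pool holds 2-4 against the weighted FA rate", {
  obs <- synthetic_observer(40, slope_db = 1.5)
  s <- sim_holdrelease_session(obs, seq(34, 46, 2), 30, seed = 8)
  pts <- psychometric_points(s$trials)
  expect_true(all(pts$pcmax >= 0 & pts$pcmax <= 1))
  expect_true(all(diff(pts$p_fa) == 0)) # session-wide FA rate
  # performance grows from near-chance to near-perfect across levels
  expect_lt(pts$pcmax[1], 0.6)
  expect_gt(pts$pcmax[nrow(pts)], 0.9)
  fit <- fit_threshold_pcmax(pts)
  expect_equal(fit$threshold_db, 40, tolerance = 2)
})

test_that("the permutation ceiling is seed-stable and separates real detection", {
  null_obs <- synthetic_observer(1000) # never detects
  s <- sim_holdrelease_session(null_obs, seq(30, 40, 2), 20, seed = 5)
  p1 <- permutation_chance(s$trials, n_perm = 400, seed = 3)
  p2 <- permutation_chance(s$trials, n_perm = 400, seed = 3)
  expect_identical(p1$pcmax_perm, p2$pcmax_perm)
  expect_identical(p1$ceiling, p2$ceiling)
  # null observer sits below the ceiling
  expect_lt(p1$observed, p1$ceiling)

  det <- synthetic_observer(30, slope_db = 1)
  s2 <- sim_holdrelease_session(det, seq(36, 44, 2), 25, seed = 6)
  p3 <- permutation_chance(s2$trials, n_perm = 400, seed = 7)
  expect_gt(p3$observed, p3$ceiling)
  expect_error(permutation_chance(s$trials[1:5, ], 100, 1), "too few")
})
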