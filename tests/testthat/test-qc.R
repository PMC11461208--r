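make_accel <- function(az, t0 = 0, ax = 0, ay = 0) {
  n <- length(az)
  data.frame(time_s = t0 + (seq_len(n) - 1L) * 0.02,
             ax = rep_len(ax, n), ay = rep_len(ay, n), az = az)
}

test_that("device-motion check smooths with a 13-frame moving average", {
  win <- fake_window()
  still <- make_accel(rep(0, 1500))
  expect_true(check_rest_motion(still, win))
  # sustained smoothed z above 0.4 fails
  shaken <- make_accel(c(rep(0, 500), rep(0.45, 100), rep(0, 900)))
  expect_false(check_rest_motion(shaken, win))
  # a single-frame spike of 0.5 is diluted to 0.5/13 ~ 0.038 and passes
  spike <- rep(0, 1500); spike[750] <- 0.5
  expect_true(check_rest_motion(make_accel(spike), win))
  # per-axis thresholds: x is the strictest
  drift <- make_accel(rep(0, 1500), ax = 0.035)
  expect_false(check_rest_motion(drift, win))
  # missing accelerometer data: warn + pass by default, fail when configured
  empty <- make_accel(numeric(0))
  expect_warning(ok <- check_rest_motion(empty, win), "no accelerometer")
  expect_true(ok)
  cfg <- qc_config(missing_accel = "fail")
  expect_false(check_rest_motion(empty, win, cfg))
})

test_that("start-latency check uses the cue with a 1.5 s allowance", {
  win <- fake_window(cue = 10, tap_start = 10, tap_end = 40, rest_end = 70)
  expect_true(check_start_latency(fake_taps(10 + c(1.4, 1.6), cue = 10), win))
  expect_false(check_start_latency(fake_taps(10 + c(1.6, 1.8), cue = 10), win))
  expect_false(check_start_latency(fake_taps(numeric(0), cue = 10), win))
})

test_that("finger-compliance check fails on wrong taps or missing fingers", {
  win <- fake_window()
  full <- fake_tracks(c("index", "middle", "ring", "little"),
                      t_began = rep(0, 4), t_ended = rep(60, 4))
  clean <- fake_taps(seq(0.5, 29.5, by = 0.2))
  expect_true(check_finger_compliance(full, clean, win))
  wrongtap <- fake_taps(seq(0.5, 29.5, by = 0.2), wrong = 15.0)
  expect_false(check_finger_compliance(full, wrongtap, win))
  # two fingers lifted for 4 s cumulative (2 s + 2 s) exceeds the 3 s allowance
  lifted <- fake_tracks(
    c("index", "middle", "middle", "middle", "ring", "little"),
    t_began = c(0, 0, 12, 22, 0, 0),
    t_ended = c(60, 10, 20, 60, 60, 60))
  tracks3 <- lifted[lifted$finger != "little" | lifted$t_began > 0, ]
  only3 <- fake_tracks(c("index", "middle", "ring"),
                       t_began = c(0, 0, 0), t_ended = c(60, 60, 60))
  expect_true(check_finger_compliance(only3, clean, win))  # 3 fingers suffice
  two <- fake_tracks(c("index", "middle", "ring"),
                     t_began = c(0, 0, 26), t_ended = c(60, 22, 60))
  # ring lifted 0-26, middle 22-26: below 3 fingers for 4 s in 22..26
  expect_false(check_finger_compliance(two, clean, win))
})

test_that("speed-profile checks bin the max into 1-2 and the min into 5-6", {
  expect_equal(unname(check_speed_profile(c(6.0, 5.8, 5.5, 5.3, 5.1, 5.0))),
               c(TRUE, TRUE))
  expect_equal(unname(check_speed_profile(c(5.0, 5.2, 5.6, 5.3, 5.1, 5.0))),
               c(FALSE, TRUE))   # max in bin 3
  expect_equal(unname(check_speed_profile(c(6.0, 5.8, 5.5, 5.0, 5.4, 5.6))),
               c(TRUE, FALSE))   # min in bin 4
  # ties: a flat curve attains its extremes everywhere and passes both
  expect_equal(unname(check_speed_profile(rep(5, 6))), c(TRUE, TRUE))
})

test_that("rest-conduct check flags taps and prolonged lifts during rest", {
  win <- fake_window()
  at_rest <- fake_tracks(c("index", "middle", "ring", "little"),
                         t_began = rep(0, 4), t_ended = rep(60, 4))
  expect_true(check_rest_conduct(at_rest, win))
  # one transient touch 10 s into rest is a tap
  tapping <- rbind(at_rest,
                   fake_tracks("index", t_began = 40, t_ended = 40.06))
  class(tapping) <- class(at_rest)
  expect_false(check_rest_conduct(tapping, win))
  # less than 4 fingers for 4 s starting 6 s into rest exceeds 3.5 s
  lifted <- fake_tracks(c("index", "middle", "ring", "little", "little"),
                        t_began = c(0, 0, 0, 0, 40),
                        t_ended = c(60, 60, 60, 36, 60))
  expect_false(check_rest_conduct(lifted, win))
  # the same lift inside the 5 s grace period is tolerated
  grace <- fake_tracks(c("index", "middle", "ring", "little", "little"),
                       t_began = c(0, 0, 0, 0, 34.8),
                       t_ended = c(60, 60, 60, 31, 60))
  expect_true(check_rest_conduct(grace, win))
})

test_that("missing-data check removes long ITIs and limits gap count/run", {
  ok <- check_missing_data(fake_taps(seq(0, 29.8, by = 0.2)))
  expect_true(ok$pass)
  expect_equal(ok$n_removed, 0L)
  one_gap <- check_missing_data(fake_taps(c(seq(0, 10, 0.2),
                                            seq(12.5, 29.8, 0.2))))
  expect_true(one_gap$pass)                     # a 2.5 s gap is removed
  expect_equal(one_gap$n_removed, 1L)
  expect_equal(sum(one_gap$taps$removed_itis), 1L)
  long_gap <- check_missing_data(fake_taps(c(seq(0, 10, 0.2),
                                             seq(16, 29.8, 0.2))))
  expect_false(long_gap$pass)                   # a 6 s run is too much
  four <- fake_taps(c(seq(0, 5, 0.2), seq(7.5, 11, 0.2), seq(13.5, 17, 0.2),
                      seq(19.5, 23, 0.2), seq(25.5, 29.8, 0.2)))
  res <- check_missing_data(four)
  expect_equal(res$n_removed, 4L)
  expect_false(res$pass)                        # more than 3 removals
})

test_that("multi-failure trials are attributed to the first failing criterion", {
  prof <- uniform_profile()
  win <- default_schedule()[1, ]
  tr <- generate_trial(prof, "index", win, rng_seed = 8)
  tr <- inject_violation(tr, violation_spec(4, 1, 15), rng_seed = 1)
  tr <- inject_violation(tr, violation_spec(1, 1, 0.8), rng_seed = 2)
  sess <- tapfatigue:::assemble_session(prof, list(tr), win, data.frame())
  tq <- evaluate_trial(sess, win)
  expect_false(tq$verdicts[["c1"]])
  expect_false(tq$verdicts[["c4"]])
  expect_equal(tq$attributed_criterion, 1L)
  expect_true(tq$excluded)
})

test_that("the exclusion cascade drops fingers strictly above 3 lost trials", {
  qc <- fake_session_qc(list(index = 3L, middle = 4L, little = 6L))
  casc <- apply_exclusion_cascade(qc)
  expect_equal(casc$fingers$finger_excluded, c(FALSE, TRUE, TRUE))
  expect_false(casc$participant_excluded)
  all_gone <- fake_session_qc(list(index = 4L, middle = 5L, little = 6L))
  expect_true(apply_exclusion_cascade(all_gone)$participant_excluded)
  none <- fake_session_qc(list(index = 0L, middle = 0L, little = 0L))
  casc <- apply_exclusion_cascade(none)
  expect_false(any(casc$fingers$finger_excluded))
  expect_equal(casc$fingers$n_valid, rep(6L, 3))
})

test_that("exclusion summary partitions attributed counts and percentages", {
  qcs <- list(fake_session_qc(list(index = 2L, middle = 0L, little = 0L)),
              fake_session_qc(list(index = 0L, middle = 0L, little = 0L),
                              id = "p2", age_group = "aged"))
  rep <- exclusion_summary(qcs)
  expect_equal(rep$n_trials_total, 36L)
  expect_equal(rep$per_criterion$n_excluded[4], 2L)
  expect_equal(rep$per_criterion$pct[4], 100 * 2 / 36)
  expect_equal(sum(rep$per_criterion$n_excluded), rep$n_trials_excluded)
  expect_equal(rep$fingers$n_valid_participants, rep(2L, 3))
  expect_equal(rep$participants$n_excluded, c(0L, 0L))
  empty <- exclusion_summary(list())
  expect_equal(empty$per_criterion$pct, rep(0, 7))
})

test_that("relaxing thresholds never increases the number of exclusions", {
  coh <- generate_cohort(cohort_config(n_young = 3, n_aged = 3, seed = 13,
                                       violation_rate = 0.25))
  strict <- qc_config()
  lax <- qc_config(start_latency_max_s = 3, iti_gap_s = 4,
                   max_gap_run_s = 10, low_finger_max_s = 6,
                   rest_low_finger_max_s = 7, accel_thresholds =
                     c(x = 0.06, y = 0.09, z = 0.8))
  n_strict <- sum(do.call(rbind, lapply(coh, evaluate_session,
                                        cfg = strict))$excluded)
  n_lax <- sum(do.call(rbind, lapply(coh, evaluate_session,
                                     cfg = lax))$excluded)
  expect_lte(n_lax, n_strict)
  expect_gt(n_strict, 0L)
})
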