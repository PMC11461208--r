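test_that("uniform tapping gives flat 6-bin curves", {
  win <- fake_window()
  bt <- bin_trial(fake_taps(seq(0, 29.8, by = 0.2)), win)
  expect_length(bt$bin_freqs, 6L)
  expect_equal(bt$bin_freqs, rep(5, 6))
  # taps only in the first 5 s: remaining bins have no coverage
  burst <- bin_trial(fake_taps(seq(0, 29 / 6, by = 1 / 6)), win)
  expect_equal(burst$bin_freqs, c(6, 0, 0, 0, 0, 0))
})

test_that("removed gaps are subtracted from the bin denominator", {
  # 5 Hz tapping with a 2.5 s dropout inside bin 3
  times <- c(seq(0, 11, 0.2), seq(13.5, 29.8, 0.2))
  cleaned <- check_missing_data(fake_taps(times))
  expect_equal(cleaned$n_removed, 1L)
  bt <- bin_trial(cleaned$taps, fake_window())
  expect_equal(bt$bin_freqs, rep(5, 6), tolerance = 1e-9)
  expect_equal(bt$bin_coverage[3], 2.5)
  # without the removal flag the gap would drag bin 3 down
  raw <- bin_trial(fake_taps(times), fake_window())
  expect_lt(raw$bin_freqs[3], 3.5)
})

test_that("binned taps are conserved: sum(freq x coverage) = intervals", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(60:160, 1)
    times <- sort(stats::runif(n, 0, 30))
    bt <- bin_trial(fake_taps(times), fake_window())
    expect_equal(sum(bt$bin_freqs * bt$bin_coverage), n - 1)
  }
})

test_that("finger aggregation averages bins over at least three trials", {
  b1 <- c(6, 5.8, 5.6, 5.4, 5.2, 5.0)
  b2 <- c(4, 3.8, 3.6, 3.4, 3.2, 3.0)
  agg <- aggregate_finger(rbind(b1, b2, (b1 + b2) / 2))
  expect_equal(agg$mean_curve, unname((b1 + b2) / 2))
  expect_equal(agg$n_valid_trials, 3L)
  expect_error(aggregate_finger(rbind(b1, b2)), "cascade")
  same <- aggregate_finger(matrix(rep(b1, 6), nrow = 6, byrow = TRUE))
  expect_equal(same$mean_curve, unname(b1))
})

test_that("decrease statistics follow the max/min definition", {
  dec <- compute_decreases(c(6.0, 5.8, 5.5, 5.3, 5.1, 5.0))
  expect_equal(dec$speed_max, 6.0)
  expect_equal(dec$speed_min, 5.0)
  expect_equal(dec$relative_decrease_pct, 100 * (1 - 5 / 6))
  expect_equal(dec$absolute_decrease_hz, 1.0)
  flat <- compute_decreases(rep(5.2, 6))
  expect_equal(flat$relative_decrease_pct, 0)
  expect_equal(flat$absolute_decrease_hz, 0)
  ratio <- compute_decreases(c(6.0, 5.8, 5.5, 5.3, 5.1, 5.0),
                             variant = "ratio")
  expect_equal(ratio$relative_decrease_pct, 100 * 5 / 6)
  zero <- compute_decreases(rep(0, 6))
  expect_true(zero$flagged)
  expect_true(is.na(zero$relative_decrease_pct))
})

test_that("decreases are shift-invariant and scale as expected", {
  set.seed(7)
  times <- cumsum(stats::runif(140, 0.15, 0.25))
  times <- times[times < 30]
  base <- compute_decreases(bin_trial(fake_taps(times),
                                      fake_window())$bin_freqs)
  shifted <- compute_decreases(
    bin_trial(fake_taps(times + 100, tap_start = 100, tap_end = 130),
              fake_window(cue = 100, tap_start = 100, tap_end = 130,
                          rest_end = 160))$bin_freqs)
  expect_equal(shifted$relative_decrease_pct, base$relative_decrease_pct)
  expect_equal(shifted$absolute_decrease_hz, base$absolute_decrease_hz)
  # uniform speed scaling: relative invariant, absolute scales linearly
  curve <- bin_trial(fake_taps(times), fake_window())$bin_freqs
  faster <- compute_decreases(2 * curve)
  expect_equal(faster$relative_decrease_pct, base$relative_decrease_pct,
               tolerance = 1e-9)
  expect_equal(faster$absolute_decrease_hz, 2 * base$absolute_decrease_hz,
               tolerance = 1e-9)
})

test_that("noise-free sessions recover the generative decrease to 1.5 pp", {
  for (d in c(0.08, 0.17, 0.30)) {
    prof <- uniform_profile(decrease = d, iti_cv = 0)
    s <- generate_session(prof, seed = 50 + round(100 * d))
    qc <- evaluate_session(s)
    expect_false(any(qc$excluded))
    feat <- compute_features(list(qc))
    expect_equal(nrow(feat), 3L)
    expect_true(all(abs(feat$rel_decrease_pct - 100 * d) < 1.5))
    expect_true(all(feat$n_valid_trials == 6L))
  }
})

test_that("feature tables honour the cascade and trial validity", {
  prof <- uniform_profile()
  # four little-finger trials carry an unambiguous violation
  little_trials <- which(default_schedule()$finger == "little")
  s <- generate_session(prof, seed = 61, violations = list(
    violation_spec(5, little_trials[1:4], 12.5)))
  # finger order is randomised per session, so map through this session
  idx <- which(s$trials$finger == "little")
  s2 <- generate_session(prof, seed = 61, violations = list(
    violation_spec(5, idx[1:4], 12.5)))
  qc <- evaluate_session(s2)
  feat <- compute_features(list(qc))
  expect_setequal(unique(feat$finger), c("index", "middle"))
  casc <- apply_exclusion_cascade(qc)
  expect_true(casc$fingers$finger_excluded[casc$fingers$finger == "little"])
})

test_that("the long time-course table matches the feature curves", {
  coh <- generate_cohort(cohort_config(n_young = 2, n_aged = 2, seed = 71,
                                       violation_rate = 0))
  feat <- compute_features(lapply(coh, evaluate_session))
  long <- time_course_table(feat)
  expect_equal(nrow(long), 6L * nrow(feat))
  expect_s3_class(long$time_bin, "factor")
  one <- long[long$participant_id == feat$participant_id[1] &
                long$finger == feat$finger[1], ]
  expect_equal(one$freq[order(one$time_bin)],
               as.numeric(feat[1, paste0("bin", 1:6)]))
})
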