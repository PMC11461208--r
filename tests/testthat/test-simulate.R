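test_that("slowing profile hits its boundary values and is monotone", {
  expect_equal(slowing_profile(0, f0 = 6, decrease = 0.17, tau = 10), 6.0)
  expect_equal(slowing_profile(30, f0 = 6, decrease = 0.17, tau = 10), 4.98)
  expect_equal(slowing_profile(15, f0 = 5, decrease = 0, tau = 10), 5.0)
  t <- seq(0, 30, by = 0.1)
  for (tau in c(2, 10, 30, 80)) {
    f <- slowing_profile(t, f0 = 6, decrease = 0.2, tau = tau)
    expect_true(all(diff(f) <= 1e-12))
    expect_equal(f[1], 6)
    expect_equal(f[length(f)], 6 * 0.8)
  }
})

test_that("slowing profile rejects invalid parameters", {
  expect_error(slowing_profile(-1, 6, 0.2, 10), "t must")
  expect_error(slowing_profile(31, 6, 0.2, 10), "t must")
  expect_error(slowing_profile(5, -1, 0.2, 10), "f0")
  expect_error(slowing_profile(5, 6, 1.0, 10), "decrease")
  expect_error(slowing_profile(5, 6, 0.2, 0), "tau")
})

test_that("profile/config constructors validate their invariants", {
  expect_error(tapper_profile("p", 40, "young", "female", "right"),
               "inconsistent")
  expect_error(tapper_profile("p", 25, "young", "female", "right",
                              f0 = c(index = -1, middle = 5, little = 5)),
               "positive")
  expect_error(tapper_profile("p", 25, "young", "female", "right",
                              iti_cv = -0.1), "iti_cv")
  expect_error(cohort_config(violation_rate = 1.5), "violation_rate")
  expect_error(cohort_config(n_young = -1), "counts")
})

test_that("a deterministic constant-rate trial emits one tap per period", {
  prof <- uniform_profile(f0 = 5, decrease = 0, iti_cv = 0)
  win <- default_schedule()[1, ]
  tr <- generate_trial(prof, "index", win, rng_seed = 1, start_latency = 0)
  own <- tr$taps[tr$taps$finger == "index", ]
  expect_equal(nrow(own), 150L)  # integral of 5 Hz over 30 s
  expect_equal(diff(own$t_began), rep(0.2, 149))
})

test_that("clean trials start tapping within the latency criterion", {
  prof <- uniform_profile()
  win <- default_schedule()[1, ]
  for (seed in 1:20) {
    tr <- generate_trial(prof, "middle", win, rng_seed = seed)
    first <- min(tr$taps$t_began[tr$taps$finger == "middle"])
    expect_lte(first - win$cue_time_s, 1.5)
    expect_gte(first, win$cue_time_s)
  }
})

test_that("trial generation is deterministic and stays inside its window", {
  prof <- uniform_profile()
  win <- default_schedule()[3, ]
  a <- generate_trial(prof, "little", win, rng_seed = 99)
  b <- generate_trial(prof, "little", win, rng_seed = 99)
  expect_identical(a, b)
  ev <- rbind(a$taps, a$rest_contacts)
  expect_true(all(ev$t_began >= win$cue_time_s))
  expect_true(all(ev$t_ended < win$rest_end_s))
  expect_true(all(a$accel$time_s >= win$cue_time_s &
                    a$accel$time_s < win$rest_end_s))
  expect_error(generate_trial(prof, "thumb", win), "finger")
})

test_that("the 18-trial schedule has the protocol's rest structure", {
  sch <- default_schedule()
  expect_equal(nrow(sch), 18L)
  expect_equal(sch$tap_end_s - sch$tap_start_s, rep(30, 18))
  rests <- sch$rest_end_s - sch$tap_end_s
  expect_equal(rests[c(6, 12)], c(60, 60))   # extended after blocks 2 and 4
  expect_equal(rests[-c(6, 12)], rep(30, 16))
  expect_equal(sch$cue_time_s[-1], sch$rest_end_s[-18])
  expect_error(trial_schedule(rep("index", 18)), "permutation")
})

test_that("generated sessions have 6 blocks with every finger once", {
  coh <- generate_cohort(cohort_config(n_young = 2, n_aged = 2, seed = 5,
                                       violation_rate = 0))
  expect_length(coh, 4L)
  for (s in coh) {
    expect_equal(nrow(s$trials), 18L)
    for (b in 1:6) {
      expect_setequal(s$trials$finger[s$trials$block == b],
                      c("index", "middle", "little"))
    }
    expect_equal(as.vector(table(s$trials$finger)[c("index", "middle",
                                                    "little")]),
                 rep(6L, 3))
    expect_s3_class(s, "tap_session")
    expect_named(s$truth, c("profile", "injections"))
  }
  ages <- vapply(coh, function(s) s$participant$age_years, numeric(1))
  grps <- vapply(coh, function(s) s$participant$age_group, character(1))
  expect_true(all(ages[grps == "young"] <= 30))
  expect_true(all(ages[grps == "aged"] >= 50))
})

test_that("cohort generation is reproducible from its seed", {
  cfg <- cohort_config(n_young = 1, n_aged = 1, seed = 77,
                       violation_rate = 0.2)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(lapply(a, unclass), lapply(b, unclass))
  d1 <- file.path(tempdir(), "cohA"); d2 <- file.path(tempdir(), "cohB")
  write_session(a[[1]], d1); write_session(b[[1]], d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("violation specs reject magnitudes inside the allowed range", {
  expect_error(violation_spec(1, 1, 0.3), "not strictly beyond")  # z <= 0.4
  expect_error(violation_spec(2, 1, 1.0), "not strictly beyond")  # <= 1.5 s
  expect_error(violation_spec(7, 1, 1.5), "not strictly beyond")  # <= 2 s
  expect_error(violation_spec(3, 1, 0), "not strictly beyond")
  expect_error(violation_spec(9, 1, 1), "criterion")
  expect_s3_class(violation_spec(1, 1, 0.8), "violation_spec")
})

test_that("injected violations reshape the streams as requested", {
  prof <- uniform_profile()
  win <- default_schedule()[1, ]
  tr <- generate_trial(prof, "index", win, rng_seed = 4)

  late <- inject_violation(tr, violation_spec(2, 1, 2.0), rng_seed = 1)
  expect_gte(min(late$taps$t_began) - win$cue_time_s, 2.0)

  shaken <- inject_violation(tr, violation_spec(1, 1, 0.8), rng_seed = 1)
  sm <- tapfatigue:::moving_average(shaken$accel$az, 13)
  expect_gt(max(abs(sm)), 0.4)

  wrong <- inject_violation(tr, violation_spec(3, 1, 2), rng_seed = 1)
  expect_equal(sum(wrong$taps$finger != "index"), 2L)

  gap <- inject_violation(tr, violation_spec(7, 1, 6), rng_seed = 1)
  own <- sort(gap$taps$t_began[gap$taps$finger == "index"])
  expect_gt(max(diff(own)), 5)
})
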