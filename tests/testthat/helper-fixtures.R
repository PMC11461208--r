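# Shared fixture builders: everything is generated in code at test time.

# A profile with identical parameters for all three tapping fingers.
uniform_profile <- function(f0 = 5.7, decrease = 0.17, tau = 30,
                            iti_cv = 0.02, handedness = "right",
                            id = "tst") {
  tapper_profile(id, age_years = 25, age_group = "young", sex = "female",
                 handedness = handedness,
                 f0 = c(index = f0, middle = f0, little = f0),
                 decrease = c(index = decrease, middle = decrease,
                              little = decrease),
                 tau = tau, iti_cv = iti_cv)
}

default_schedule <- function() {
  trial_schedule(rep(c("index", "middle", "little"), 6))
}

# A hand-built minimal tap_series for unit tests of single criteria.
fake_taps <- function(times, cue = 0, tap_start = 0, tap_end = 30,
                      wrong = numeric(0)) {
  structure(list(tap_times_s = times, itis_s = diff(times),
                 wrong_finger_times_s = wrong,
                 trial_index = 1L, finger = "index",
                 cue_time_s = cue, tap_start_s = tap_start,
                 tap_end_s = tap_end),
            class = "tap_series")
}

# Hand-built finger tracks (contact intervals).
fake_tracks <- function(finger, t_began, t_ended, x = 0.5, y = 0.35) {
  structure(data.frame(pointer_id = seq_along(finger), finger = finger,
                       t_began = t_began, t_ended = t_ended, x = x, y = y),
            class = c("finger_tracks", "data.frame"))
}

# One-row trial window.
fake_window <- function(cue = 0, tap_start = 0, tap_end = 30,
                        rest_end = 60, finger = "index", idx = 1L) {
  data.frame(trial_index = idx, block = 1L, finger = finger,
             cue_time_s = cue, tap_start_s = tap_start,
             tap_end_s = tap_end, rest_end_s = rest_end)
}

# A synthetic per-trial verdict table with a given number of excluded
# trials per finger (for cascade/summary unit tests).
fake_session_qc <- function(excluded_per_finger, id = "p1",
                            age_group = "young") {
  rows <- do.call(rbind, lapply(names(excluded_per_finger), function(f) {
    exc <- c(rep(TRUE, excluded_per_finger[[f]]),
             rep(FALSE, 6 - excluded_per_finger[[f]]))
    data.frame(participant_id = id, age_years = 25, age_group = age_group,
               sex = "female", trial_index = seq_along(exc), block = 1:6,
               finger = f, excluded = exc,
               attributed_criterion = ifelse(exc, 4L, NA_integer_))
  }))
  class(rows) <- c("session_qc", "data.frame")
  rows
}

# Per-trial relative decreases of one session_qc table.
per_trial_decreases <- function(qc) {
  vapply(seq_len(nrow(qc)), function(i) {
    compute_decreases(as.numeric(qc[i, paste0("bin", 1:6)]))$relative_decrease_pct
  }, numeric(1))
}
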