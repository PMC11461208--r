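#' Quality-control configuration
#'
#' Thresholds of the seven trial-validity criteria and the exclusion
#' cascade. Defaults follow the task's published protocol: device motion is
#' flagged when the accelerometer, smoothed with a 0.25 s moving average,
#' exceeds 0.03/0.045/0.4 (x/y/z, device units) during tapping; tapping must
#' start within 1.5 s of the cue; at least 3 non-thumb fingers must touch
#' the screen (shortfalls allowed for at most 3 s cumulative); the maximal
#' tapping frequency must fall in the first 10 s and the minimal in the last
#' 10 s; during rest no tapping is allowed and, after a 5 s grace period,
#' fewer than 4 resting fingers for at most 3.5 s; inter-tap intervals over
#' 2 s are removed, with at most 3 removals and no gap over 5 s; a finger
#' with more than 3 of its 6 trials removed is dropped.
#'
#' @param accel_smooth_window_s moving-average window, seconds.
#' @param accel_thresholds named vector `x`, `y`, `z` of absolute smoothed
#'   acceleration limits.
#' @param start_latency_max_s latest allowed first tap after the cue.
#' @param min_fingers_on_screen minimum simultaneous fingers while tapping.
#' @param low_finger_max_s allowed cumulative shortfall time while tapping.
#' @param early_max_window_s the frequency maximum must occur within this
#'   many seconds from trial start.
#' @param late_min_window_s the frequency minimum must occur within this
#'   many seconds of trial end.
#' @param rest_grace_s rest seconds exempt from the resting finger count.
#' @param rest_low_finger_max_s allowed cumulative time with fewer than 4
#'   resting fingers after the grace period.
#' @param rest_tap_max_contact_s longest screen contact still counted as a
#'   tap (longer contacts are resting placements).
#' @param iti_gap_s inter-tap intervals longer than this are removed.
#' @param max_gap_count maximum number of removed intervals per trial.
#' @param max_gap_run_s longest acceptable single gap.
#' @param max_removed_trials_per_finger a finger is excluded when more
#'   trials than this are removed.
#' @param missing_accel what to do when a trial has no accelerometer data:
#'   `"warn_pass"` (default) or `"fail"`.
#' @return an object of class `qc_config`.
#' @export
qc_config <- function(accel_smooth_window_s = 0.25,
                      accel_thresholds = c(x = 0.03, y = 0.045, z = 0.4),
                      start_latency_max_s = 1.5,
                      min_fingers_on_screen = 3L,
                      low_finger_max_s = 3.0,
                      early_max_window_s = 10,
                      late_min_window_s = 10,
                      rest_grace_s = 5,
                      rest_low_finger_max_s = 3.5,
                      rest_tap_max_contact_s = 1,
                      iti_gap_s = 2.0,
                      max_gap_count = 3L,
                      max_gap_run_s = 5.0,
                      max_removed_trials_per_finger = 3L,
                      missing_accel = c("warn_pass", "fail")) {
  missing_accel <- match.arg(missing_accel)
  vals <- c(accel_smooth_window_s, accel_thresholds, start_latency_max_s,
            low_finger_max_s, early_max_window_s, late_min_window_s,
            rest_grace_s, rest_low_finger_max_s, rest_tap_max_contact_s,
            iti_gap_s, max_gap_run_s)
  if (any(vals <= 0)) stop_param("all durations and thresholds must be > 0")
  structure(list(
    accel_smooth_window_s = accel_smooth_window_s,
    accel_thresholds = accel_thresholds,
    start_latency_max_s = start_latency_max_s,
    min_fingers_on_screen = as.integer(min_fingers_on_screen),
    low_finger_max_s = low_finger_max_s,
    early_max_window_s = early_max_window_s,
    late_min_window_s = late_min_window_s,
    rest_grace_s = rest_grace_s,
    rest_low_finger_max_s = rest_low_finger_max_s,
    rest_tap_max_contact_s = rest_tap_max_contact_s,
    iti_gap_s = iti_gap_s,
    max_gap_count = as.integer(max_gap_count),
    max_gap_run_s = max_gap_run_s,
    max_removed_trials_per_finger = as.integer(max_removed_trials_per_finger),
    missing_accel = missing_accel), class = "qc_config")
}

#' Criterion 1: perform the task at rest (device motion)
#'
#' Smooths each accelerometer axis inside the tap window with a centred
#' moving average (13 frames at 50 Hz for the default 0.25 s window, edges
#' truncated) and fails the trial if any smoothed sample exceeds the
#' per-axis threshold in absolute value.
#'
#' @param accel accelerometer data.frame (`time_s`, `ax`, `ay`, `az`).
#' @param trial one row of the trial schedule.
#' @param cfg a [qc_config()].
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
check_rest_motion <- function(accel, trial, cfg = qc_config()) {
  sel <- accel$time_s >= trial$tap_start_s & accel$time_s < trial$tap_end_s
  if (!any(sel)) {
    if (cfg$missing_accel == "fail") return(FALSE)
    warning(sprintf("trial %s: no accelerometer data in tap window; passing",
                    trial$trial_index), call. = FALSE)
    return(TRUE)
  }
  dt <- stats::median(diff(accel$time_s[sel]))
  if (!length(dt) || !is.finite(dt) || dt <= 0) dt <- FRAME_DT
  k <- 2L * floor(cfg$accel_smooth_window_s / dt / 2) + 1L  # odd, ~0.25 s
  th <- cfg$accel_thresholds
  for (axis in c("x", "y", "z")) {
    sm <- moving_average(accel[[paste0("a", axis)]][sel], k)
    if (any(abs(sm) > th[[axis]])) return(FALSE)
  }
  TRUE
}

#' Criterion 2: focus on the experiment (start latency)
#'
#' Fails when the first tap comes more than `start_latency_max_s` after the
#' starting cue, or when the trial contains no taps at all.
#'
#' @param taps a `tap_series` from [detect_taps()].
#' @inheritParams check_rest_motion
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
check_start_latency <- function(taps, trial, cfg = qc_config()) {
  if (!length(taps$tap_times_s)) return(FALSE)
  (taps$tap_times_s[1L] - trial$cue_time_s) <= cfg$start_latency_max_s
}

#' Criterion 3: tap with the instructed finger, keep the others down
#'
#' Fails when any wrong-finger tap occurs inside the tap window, or when
#' the cumulative time with fewer than `min_fingers_on_screen` non-thumb
#' fingers on the screen exceeds `low_finger_max_s`.
#'
#' @param tracks a `finger_tracks` data.frame.
#' @param taps a `tap_series` (supplies the wrong-finger events).
#' @inheritParams check_rest_motion
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
check_finger_compliance <- function(tracks, taps, trial, cfg = qc_config()) {
  if (length(taps$wrong_finger_times_s)) return(FALSE)
  low <- time_below_count(tracks$t_began, tracks$t_ended,
                          trial$tap_start_s, trial$tap_end_s,
                          cfg$min_fingers_on_screen)
  low <= cfg$low_finger_max_s
}

#' Criteria 4 and 5: tap as fast as possible from the beginning to the end
#'
#' Operates on the six 5 s bin frequencies of a trial. Criterion 4 passes
#' when some bin attaining the maximal frequency lies in the first 10 s
#' (bins 1-2); criterion 5 passes when some bin attaining the minimal
#' frequency lies in the last 10 s (bins 5-6).
#'
#' @param bin_freqs numeric vector of 6 bin frequencies, Hz.
#' @param cfg a [qc_config()].
#' @return named logical vector `c(criterion4 = ..., criterion5 = ...)`.
#' @export
check_speed_profile <- function(bin_freqs, cfg = qc_config()) {
  stopifnot(length(bin_freqs) == 6L)
  n_early <- ceiling(cfg$early_max_window_s / 5)
  n_late <- ceiling(cfg$late_min_window_s / 5)
  at_max <- which(bin_freqs >= max(bin_freqs) - 1e-9)
  at_min <- which(bin_freqs <= min(bin_freqs) + 1e-9)
  c(criterion4 = any(at_max <= n_early),
    criterion5 = any(at_min > 6L - n_late))
}

#' Criterion 6: rest during the break
#'
#' Fails when any tap (transient contact shorter than
#' `rest_tap_max_contact_s`) begins during the rest window, or when -- after
#' the first `rest_grace_s` seconds of rest -- the cumulative time with
#' fewer than four fingers on the screen exceeds `rest_low_finger_max_s`.
#'
#' @inheritParams check_finger_compliance
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
check_rest_conduct <- function(tracks, trial, cfg = qc_config()) {
  dur <- tracks$t_ended - tracks$t_began
  rest_tap <- tracks$t_began >= trial$tap_end_s &
    tracks$t_began < trial$rest_end_s & dur <= cfg$rest_tap_max_contact_s
  if (any(rest_tap)) return(FALSE)
  low <- time_below_count(tracks$t_began, tracks$t_ended,
                          trial$tap_end_s + cfg$rest_grace_s,
                          trial$rest_end_s, 4L)
  low <= cfg$rest_low_finger_max_s
}

#' Criterion 7: technical failures (missing data)
#'
#' Inter-tap intervals longer than `iti_gap_s` are treated as missing data
#' and removed from the series used for frequency computation. The trial
#' fails when more than `max_gap_count` intervals are removed or any single
#' gap exceeds `max_gap_run_s`.
#'
#' @param taps a `tap_series`.
#' @param cfg a [qc_config()].
#' @return list with elements `pass` (logical), `taps` (the series with a
#'   logical `removed_itis` flag per interval), `n_removed`, `max_gap_s`.
#' @export
check_missing_data <- function(taps, cfg = qc_config()) {
  removed <- taps$itis_s > cfg$iti_gap_s
  taps$removed_itis <- removed
  max_gap <- if (length(taps$itis_s)) max(taps$itis_s) else 0
  list(pass = sum(removed) <= cfg$max_gap_count &&
         max_gap <= cfg$max_gap_run_s,
       taps = taps,
       n_removed = sum(removed),
       max_gap_s = max_gap)
}

#' Evaluate all seven quality criteria for one trial
#'
#' Runs the criteria in their published order 1-7, records every verdict,
#' and attributes the exclusion to the lowest-numbered failing criterion.
#' Criteria 4 and 5 are computed on the six 5 s bin frequencies of the
#' criterion-7-cleaned tap series.
#'
#' @param session a `tap_session`.
#' @param trial one row of `session$trials`.
#' @param cfg a [qc_config()].
#' @param tracks optional precomputed [assign_fingers()] result.
#' @return a `trial_qc` list: `trial_index`, `finger`, `verdicts` (named
#'   logical, `TRUE` = pass), `excluded`, `attributed_criterion` (or `NA`),
#'   the cleaned `taps`, `bin_freqs`, `n_removed_itis`, `max_gap_s`.
#' @export
evaluate_trial <- function(session, trial, cfg = qc_config(),
                           tracks = NULL) {
  if (is.null(tracks)) tracks <- assign_fingers(session)
  taps <- detect_taps(tracks, trial,
                      tap_max_contact_s = cfg$rest_tap_max_contact_s)
  md <- check_missing_data(taps, cfg)
  bins <- bin_trial(md$taps, trial)
  speed <- check_speed_profile(bins$bin_freqs, cfg)
  verdicts <- c(
    c1 = check_rest_motion(session$accel, trial, cfg),
    c2 = check_start_latency(taps, trial, cfg),
    c3 = check_finger_compliance(tracks, taps, trial, cfg),
    c4 = unname(speed["criterion4"]),
    c5 = unname(speed["criterion5"]),
    c6 = check_rest_conduct(tracks, trial, cfg),
    c7 = md$pass)
  failing <- which(!verdicts)
  structure(list(trial_index = trial$trial_index, finger = trial$finger,
                 verdicts = verdicts, excluded = length(failing) > 0L,
                 attributed_criterion = if (length(failing))
                   unname(failing[1L]) else NA_integer_,
                 taps = md$taps, bin_freqs = bins$bin_freqs,
                 n_removed_itis = md$n_removed, max_gap_s = md$max_gap_s),
            class = "trial_qc")
}

#' Evaluate a whole session
#'
#' Applies [evaluate_trial()] to all 18 trials and returns a tidy per-trial
#' verdict table with the bin frequencies attached.
#'
#' @param session a `tap_session`.
#' @param cfg a [qc_config()].
#' @return a `session_qc` data.frame: one row per trial with columns
#'   `participant_id`, `age_group`, `sex`, `trial_index`, `block`, `finger`,
#'   `c1`..`c7` (`TRUE` = pass), `excluded`, `attributed_criterion`,
#'   `n_removed_itis`, `max_gap_s`, `n_taps`, `bin1`..`bin6`.
#' @export
evaluate_session <- function(session, cfg = qc_config()) {
  tracks <- assign_fingers(session)
  rows <- lapply(seq_len(nrow(session$trials)), function(k) {
    tq <- evaluate_trial(session, session$trials[k, ], cfg, tracks = tracks)
    cbind(
      data.frame(participant_id = session$participant$participant_id,
                 age_years = session$participant$age_years,
                 age_group = session$participant$age_group,
                 sex = session$participant$sex,
                 trial_index = tq$trial_index,
                 block = session$trials$block[k], finger = tq$finger),
      as.data.frame(as.list(tq$verdicts)),
      data.frame(excluded = tq$excluded,
                 attributed_criterion = tq$attributed_criterion,
                 n_removed_itis = tq$n_removed_itis,
                 max_gap_s = tq$max_gap_s,
                 n_taps = length(tq$taps$tap_times_s)),
      stats::setNames(as.data.frame(as.list(tq$bin_freqs)),
                      paste0("bin", 1:6)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("session_qc", "data.frame")
  out
}

#' Trial-to-finger-to-participant exclusion cascade
#'
#' A finger is excluded when more than `max_removed_trials_per_finger`
#' (default 3) of its 6 trials are excluded; a participant is excluded when
#' all three tapping fingers are excluded.
#'
#' @param session_qc a `session_qc` table for one participant.
#' @param cfg a [qc_config()].
#' @return list with `fingers` (data.frame: `finger`, `n_trials`,
#'   `n_excluded`, `n_valid`, `finger_excluded`) and `participant_excluded`.
#' @export
apply_exclusion_cascade <- function(session_qc, cfg = qc_config()) {
  stopifnot(length(unique(session_qc$participant_id)) == 1L)
  fingers <- do.call(rbind, lapply(FINGERS_TAPPING, function(f) {
    sub <- session_qc[session_qc$finger == f, ]
    n_exc <- sum(sub$excluded)
    data.frame(finger = f, n_trials = nrow(sub), n_excluded = n_exc,
               n_valid = nrow(sub) - n_exc,
               finger_excluded = n_exc > cfg$max_removed_trials_per_finger)
  }))
  list(fingers = fingers,
       participant_excluded = all(fingers$finger_excluded))
}

#' Cohort-level exclusion report
#'
#' Aggregates per-trial verdicts across a cohort: the percentage of all
#' trials attributed to each criterion (first-fail attribution in the order
#' 1-7), valid-participant counts per finger after the exclusion cascade,
#' and fully-excluded participant counts per age group.
#'
#' @param qc_list list of `session_qc` tables (one per participant), e.g.
#'   from `lapply(cohort, evaluate_session)`.
#' @param cfg a [qc_config()].
#' @return an `exclusion_report` list with elements `per_criterion`,
#'   `fingers`, `participants`, `n_trials_total`, `n_trials_excluded`.
#' @export
exclusion_summary <- function(qc_list, cfg = qc_config()) {
  if (!length(qc_list)) {
    return(structure(list(
      per_criterion = data.frame(criterion = 1:7, n_excluded = 0L, pct = 0),
      fingers = data.frame(finger = FINGERS_TAPPING, n_valid_participants = 0L),
      participants = data.frame(age_group = c("young", "aged"), n = 0L,
                                n_excluded = 0L, pct_excluded = 0),
      n_trials_total = 0L, n_trials_excluded = 0L),
      class = "exclusion_report"))
  }
  all_trials <- do.call(rbind, qc_list)
  n_total <- nrow(all_trials)
  per_criterion <- data.frame(
    criterion = 1:7,
    n_excluded = vapply(1:7, function(cr) {
      sum(all_trials$attributed_criterion == cr, na.rm = TRUE)
    }, integer(1L)))
  per_criterion$pct <- 100 * per_criterion$n_excluded / n_total
  cascades <- lapply(qc_list, apply_exclusion_cascade, cfg = cfg)
  finger_valid <- vapply(FINGERS_TAPPING, function(f) {
    sum(vapply(cascades, function(cs) {
      !cs$fingers$finger_excluded[cs$fingers$finger == f]
    }, logical(1L)))
  }, integer(1L))
  meta <- do.call(rbind, lapply(seq_along(qc_list), function(i) {
    data.frame(age_group = qc_list[[i]]$age_group[1L],
               excluded = cascades[[i]]$participant_excluded)
  }))
  participants <- do.call(rbind, lapply(c("young", "aged"), function(g) {
    sub <- meta[meta$age_group == g, ]
    data.frame(age_group = g, n = nrow(sub), n_excluded = sum(sub$excluded),
               pct_excluded = if (nrow(sub)) 100 * mean(sub$excluded) else 0)
  }))
  structure(list(
    per_criterion = per_criterion,
    fingers = data.frame(finger = FINGERS_TAPPING,
                         n_valid_participants = finger_valid),
    participants = participants,
    n_trials_total = n_total,
    n_trials_excluded = sum(all_trials$excluded)),
    class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("<exclusion_report> %d trials, %d excluded (%.1f%%)\n",
              x$n_trials_total, x$n_trials_excluded,
              if (x$n_trials_total) 100 * x$n_trials_excluded /
                x$n_trials_total else 0))
  cat("Excluded trials by criterion (% of all trials):\n")
  for (i in 1:7) {
    cat(sprintf("  %d. %-55s %5.1f\n", i, criterion_labels[i],
                x$per_criterion$pct[i]))
  }
  cat("Valid participants per finger: ",
      paste(sprintf("%s=%d", x$fingers$finger,
                    x$fingers$n_valid_participants), collapse = "  "), "\n")
  for (i in seq_len(nrow(x$participants))) {
    p <- x$participants[i, ]
    cat(sprintf("Fully excluded %s participants: %d of %d (%.1f%%)\n",
                p$age_group, p$n_excluded, p$n, p$pct_excluded))
  }
  invisible(x)
}

criterion_labels <- c(
  "Perform task at rest (device motion)",
  "Focus on experiment (start latency)",
  "Tap with instructed finger, keep others on screen",
  "Tap as fast as possible from the beginning",
  "Do not change tapping strategy",
  "Do not tap during rest period",
  "Technical failure (missing data)")
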