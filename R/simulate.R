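#' Within-trial tapping-speed profile
#'
#' Instantaneous tapping frequency at time `t` of a 30 s maximal-speed trial.
#' The speed is held at the initial rate `f0` over the first 5 s, declines
#' along a saturating-exponential ramp, and settles on a floor of
#' `f0 * (1 - decrease)` over the final bin, so that the time averages of
#' the first and last 5 s bins equal `f0` and `f0 * (1 - decrease)` exactly.
#' This makes the generative `decrease` parameter coincide with the binned
#' relative-decrease estimand computed by [compute_decreases()] (see the
#' package vignette for the rationale).
#'
#' @param t time since the start of tapping, seconds, in `[0, 30]`.
#'   Vectorised.
#' @param f0 initial tapping speed, Hz (> 0).
#' @param decrease fractional speed loss over the trial, in `[0, 1)`.
#' @param tau ramp time constant in seconds (> 0); small values give a
#'   sharply saturating drop, large values an almost linear decline.
#' @param t_hold seconds during which the initial speed is held.
#' @param t_floor time at which the floor speed is reached.
#' @return tapping frequency in Hz, same length as `t`; `f(0) = f0`,
#'   `f(30) = f0 * (1 - decrease)`, monotone non-increasing in `t`.
#' @examples
#' slowing_profile(0, f0 = 6, decrease = 0.17, tau = 10)   # 6.0
#' slowing_profile(30, f0 = 6, decrease = 0.17, tau = 10)  # 4.98
#' @export
slowing_profile <- function(t, f0, decrease, tau, t_hold = 5,
                            t_floor = 22.5) {
  if (any(t < 0 | t > 30)) stop_param("t must lie in [0, 30]")
  if (f0 <= 0) stop_param("f0 must be > 0")
  if (decrease < 0 || decrease >= 1) stop_param("decrease must be in [0, 1)")
  if (tau <= 0) stop_param("tau must be > 0")
  ramp <- t_floor - t_hold
  s <- pmin(pmax(t - t_hold, 0), ramp)
  g <- (1 - exp(-s / tau)) / (1 - exp(-ramp / tau))
  f0 * (1 - decrease * g)
}

slowing_rate_fn <- function(profile, finger) {
  f0 <- profile$f0[[finger]]
  d <- profile$decrease[[finger]]
  tau <- profile$tau
  function(t) slowing_profile(t, f0, d, tau)
}

# Draw tap onset times (seconds since the starting cue) for a 30 s trial.
# ITIs are 1/rate at the current time, multiplied by unit-mean log-normal
# jitter with coefficient of variation `cv`.
synth_onsets <- function(rate_fn, duration = 30, cv = 0, latency = 0) {
  sdlog <- sqrt(log1p(cv^2))
  onsets <- numeric(ceiling(duration * 9) + 8L)
  t <- latency
  n <- 0L
  while (t < duration) {
    n <- n + 1L
    onsets[n] <- t
    iti <- 1 / rate_fn(min(t, duration))
    if (cv > 0) iti <- iti * exp(stats::rnorm(1L, -sdlog^2 / 2, sdlog))
    t <- t + iti
  }
  onsets[seq_len(n)]
}

home_positions <- function(handedness) {
  if (handedness == "left") rev(1 - HOME_X_RIGHT)[FINGERS_ALL] else HOME_X_RIGHT
}

# A contact table: one row per screen contact.
contact_df <- function(finger = character(0), t_began = numeric(0),
                       t_ended = numeric(0), x = numeric(0),
                       y = numeric(0)) {
  data.frame(finger = finger, t_began = t_began, t_ended = t_ended,
             x = x, y = y)
}

# Convert instructed-finger onsets into short tap contacts.
tap_contacts <- function(onsets, finger, home_x, y = 0.55) {
  if (!length(onsets)) return(contact_df())
  began <- snap_frame(onsets)
  ended <- began + 3 * FRAME_DT
  contact_df(finger = rep(finger, length(began)), t_began = began,
             t_ended = ended,
             x = round(home_x + stats::rnorm(length(began), 0, 0.006), 4),
             y = rep(y, length(began)))
}

accel_noise <- function(from, to, sd = c(ax = 0.002, ay = 0.003, az = 0.05)) {
  t <- frame_grid(from, to)
  data.frame(time_s = t,
             ax = round(stats::rnorm(length(t), 0, sd[["ax"]]), 5),
             ay = round(stats::rnorm(length(t), 0, sd[["ay"]]), 5),
             az = round(stats::rnorm(length(t), 0, sd[["az"]]), 5))
}

build_tap_trial <- function(profile, finger, window, start_latency = NULL) {
  homes <- home_positions(profile$handedness)
  w0 <- window$cue_time_s
  w1 <- window$rest_end_s
  latency <- start_latency %||% stats::runif(1L, 0.3, 0.8)
  onsets <- synth_onsets(slowing_rate_fn(profile, finger),
                         duration = window$tap_end_s - window$tap_start_s,
                         cv = profile$iti_cv, latency = latency)
  taps <- tap_contacts(onsets + window$tap_start_s, finger, homes[[finger]])
  # frame snapping must not push the last onset into the rest window
  taps <- taps[taps$t_began < window$tap_end_s, , drop = FALSE]
  resting <- setdiff(FINGERS_ALL, finger)
  rest <- contact_df(
    finger = c(resting, finger),
    t_began = c(rep(w0, 3L), snap_frame(window$tap_end_s + 0.4)),
    t_ended = rep(snap_frame(w1) - FRAME_DT, 4L),
    x = round(homes[c(resting, finger)], 4),
    y = rep(0.35, 4L))
  structure(list(window = window, finger = finger, profile = profile,
                 taps = taps, rest_contacts = rest,
                 accel = accel_noise(w0, w1)),
            class = "tap_trial")
}

#' Generate the raw event streams of one tapping trial
#'
#' Synthesises frame-aligned (50 Hz) touch contacts and accelerometer noise
#' for a single trial: short `began`/`ended` touch pairs for the instructed
#' finger whose inter-tap intervals follow the participant's
#' [slowing_profile()], continuous resting contacts for the non-tapping
#' fingers (the thumb is never on the screen), and low-amplitude device
#' noise well below the motion-check thresholds.
#'
#' @param profile a [tapper_profile()].
#' @param finger `"index"`, `"middle"` or `"little"`.
#' @param window one row of a trial schedule as built by [trial_schedule()]
#'   (columns `cue_time_s`, `tap_start_s`, `tap_end_s`, `rest_end_s`).
#' @param rng_seed integer seed; identical arguments give identical streams.
#' @param start_latency optional fixed delay (s) between the cue and the
#'   first tap; by default drawn uniformly from 0.3-0.8 s, safely below the
#'   1.5 s start-latency criterion.
#' @return an object of class `tap_trial`: a list with the trial `window`,
#'   the instructed `finger`, tap and resting contact tables, and an `accel`
#'   sample table, all within `[window$cue_time_s, window$rest_end_s)`.
#' @export
generate_trial <- function(profile, finger, window, rng_seed = 1L,
                           start_latency = NULL) {
  finger <- match_arg_chr(finger, FINGERS_TAPPING, "finger")
  set.seed(rng_seed)
  build_tap_trial(profile, finger, window, start_latency)
}

#' Trial schedule for one session
#'
#' Builds the 18-trial schedule: 6 blocks in which each of the index, middle
#' and little fingers taps once, in the given (typically randomised) order.
#' Every trial is 30 s of tapping followed by a 30 s break; the break is
#' extended by 30 s after blocks 2 and 4.
#'
#' @param finger_order character vector of length 18 (blocks of three, each
#'   a permutation of the tapping fingers).
#' @param session_start_s time of the first cue, seconds.
#' @return data.frame with columns `trial_index`, `block`, `finger`,
#'   `cue_time_s`, `tap_start_s`, `tap_end_s`, `rest_end_s`.
#' @export
trial_schedule <- function(finger_order, session_start_s = 5) {
  stopifnot(length(finger_order) == 18L)
  for (b in 1:6) {
    blk <- finger_order[(3 * b - 2):(3 * b)]
    if (!setequal(blk, FINGERS_TAPPING)) {
      stop_param("block %d is not a permutation of the tapping fingers", b)
    }
  }
  cue <- numeric(18)
  rest_end <- numeric(18)
  t <- session_start_s
  for (k in 1:18) {
    cue[k] <- t
    extra <- if (k %in% c(6L, 12L)) 30 else 0
    rest_end[k] <- cue[k] + 30 + 30 + extra
    t <- rest_end[k]
  }
  data.frame(trial_index = 1:18, block = rep(1:6, each = 3L),
             finger = finger_order, cue_time_s = cue, tap_start_s = cue,
             tap_end_s = cue + 30, rest_end_s = rest_end)
}

#' Inject a quality-control violation into a generated trial
#'
#' Corrupts the event streams of a [generate_trial()] result so that the
#' trial unambiguously fails exactly the requested criterion (and, for
#' magnitudes that isolate the defect, no other criterion).
#'
#' @param trial a `tap_trial` object.
#' @param spec a [violation_spec()]; `spec$trial_indices` is ignored here
#'   (it routes injections inside [generate_cohort()]).
#' @param rng_seed integer seed for the stochastic parts of the corruption.
#' @param cfg a [qc_config()] used for re-synthesis bounds.
#' @return the modified `tap_trial`.
#' @export
inject_violation <- function(trial, spec, rng_seed = 1L, cfg = qc_config()) {
  stopifnot(inherits(trial, "tap_trial"), inherits(spec, "violation_spec"))
  set.seed(rng_seed)
  w <- trial$window
  m <- spec$magnitude
  switch(spec$criterion,
    { # 1: device motion -- a 2 s block of constant z offset; the centred
      #    moving average equals the offset inside the block
      sel <- trial$accel$time_s >= w$tap_start_s + 10 &
        trial$accel$time_s < w$tap_start_s + 12
      trial$accel$az[sel] <- round(trial$accel$az[sel] + m, 5)
    },
    { # 2: late start -- drop taps before cue + magnitude
      keep <- trial$taps$t_began >= w$cue_time_s + m
      trial$taps <- trial$taps[keep, , drop = FALSE]
    },
    { # 3: wrong-finger taps -- another tapping-capable finger briefly lifts
      #    from rest and taps `m` times mid-trial
      wrong <- setdiff(FINGERS_TAPPING, trial$finger)[1L]
      times <- w$tap_start_s + 12 + 1.2 * (seq_len(m) - 1L)
      homes <- home_positions(trial$profile$handedness)
      wrong_taps <- tap_contacts(times, wrong, homes[[wrong]])
      trial <- cut_rest_contact(trial, wrong,
                                min(times) - 0.15,
                                max(times) + 0.35)
      trial$taps <- rbind(trial$taps, wrong_taps)
    },
    { # 4: ramp-up -- re-synthesise taps so the frequency peaks at t = m
      f0 <- trial$profile$f0[[trial$finger]]
      rate <- function(t) {
        f0 * ifelse(t <= m, 0.88 + 0.18 * t / m,
                    1.06 - 0.26 * (t - m) / (30 - m))
      }
      trial <- resynth_taps(trial, rate)
    },
    { # 5: late speed-up -- frequency dips to its minimum at t = m, then
      #    recovers (a change of tapping strategy)
      f0 <- trial$profile$f0[[trial$finger]]
      rate <- function(t) {
        f0 * ifelse(t <= m, 1.0 - 0.22 * t / m,
                    0.78 + 0.17 * (t - m) / (30 - m))
      }
      trial <- resynth_taps(trial, rate)
    },
    { # 6: tapping during rest -- the instructed finger lifts from its rest
      #    placement and taps `m` times starting 7 s into the break
      times <- w$tap_end_s + 7 + 0.45 * (seq_len(m) - 1L)
      homes <- home_positions(trial$profile$handedness)
      rest_taps <- tap_contacts(times, trial$finger,
                                homes[[trial$finger]], y = 0.35)
      trial <- cut_rest_contact(trial, trial$finger,
                                min(times) - 0.15, max(times) + 0.35)
      trial$taps <- rbind(trial$taps, rest_taps)
    },
    { # 7: missing data -- gaps in the tap stream; one long gap if the
      #    magnitude exceeds the 5 s run allowance, else four repeated gaps
      #    to exceed the allowed count
      starts <- if (m > 5) w$tap_start_s + 10.5 else
        w$tap_start_s + c(6, 11.5, 17, 22.5)
      for (s in starts) {
        drop <- trial$taps$finger == trial$finger &
          trial$taps$t_began > s & trial$taps$t_began < s + m
        trial$taps <- trial$taps[!drop, , drop = FALSE]
      }
    })
  trial$taps <- trial$taps[order(trial$taps$t_began), , drop = FALSE]
  trial
}

cut_rest_contact <- function(trial, finger, from, to) {
  rc <- trial$rest_contacts
  i <- which(rc$finger == finger & rc$t_began < from & rc$t_ended > to)
  if (!length(i)) stop_param("no rest contact of the %s finger spans %.1f-%.1f s",
                             finger, from, to)
  i <- i[1L]
  tail_row <- rc[i, ]
  rc$t_ended[i] <- snap_frame(from)
  tail_row$t_began <- snap_frame(to)
  trial$rest_contacts <- rbind(rc, tail_row)
  trial
}

resynth_taps <- function(trial, rate_fn) {
  w <- trial$window
  onsets <- synth_onsets(rate_fn,
                         duration = w$tap_end_s - w$tap_start_s,
                         cv = trial$profile$iti_cv,
                         latency = stats::runif(1L, 0.3, 0.8))
  homes <- home_positions(trial$profile$handedness)
  keep <- trial$taps$finger != trial$finger
  new_taps <- tap_contacts(onsets + w$tap_start_s, trial$finger,
                           homes[[trial$finger]])
  new_taps <- new_taps[new_taps$t_began < w$tap_end_s, , drop = FALSE]
  trial$taps <- rbind(trial$taps[keep, , drop = FALSE], new_taps)
  trial
}

# Default injected magnitudes: >= 1.5x the corresponding threshold (or an
# unambiguous count / time for the count- and time-based criteria).
default_violation_magnitude <- function(criterion) {
  c(0.6, 2.25, 3, 15, 12.5, 3, 7.5)[criterion]
}

# Assemble tap_trial objects into a session object.
assemble_session <- function(profile, trials, schedule, injections) {
  contacts <- do.call(rbind, lapply(trials, function(tr) {
    rbind(tr$taps, tr$rest_contacts)
  }))
  contacts <- contacts[order(contacts$t_began, contacts$x), , drop = FALSE]
  contacts$pointer_id <- seq_len(nrow(contacts))
  touches <- contacts_to_events(contacts)
  accel <- do.call(rbind, c(list(accel_noise(0, schedule$cue_time_s[1L])),
                            lapply(trials, `[[`, "accel")))
  participant <- data.frame(
    participant_id = profile$participant_id, age_years = profile$age_years,
    age_group = profile$age_group, sex = profile$sex,
    handedness = profile$handedness, device = "synthetic")
  structure(list(participant = participant, trials = schedule,
                 touches = touches, accel = accel,
                 truth = list(profile = unclass(profile),
                              injections = injections)),
            class = "tap_session")
}

contacts_to_events <- function(contacts) {
  n <- nrow(contacts)
  # sparse `moved` samples every 10 s keep long resting contacts honest
  moved <- lapply(seq_len(n), function(i) {
    if (contacts$t_ended[i] - contacts$t_began[i] < 10) return(NULL)
    t <- seq(contacts$t_began[i] + 10, contacts$t_ended[i] - 1, by = 10)
    data.frame(time_s = snap_frame(t), pointer_id = contacts$pointer_id[i],
               x = contacts$x[i], y = contacts$y[i], phase = "moved")
  })
  ev <- rbind(
    data.frame(time_s = contacts$t_began, pointer_id = contacts$pointer_id,
               x = contacts$x, y = contacts$y, phase = "began"),
    do.call(rbind, moved),
    data.frame(time_s = contacts$t_ended, pointer_id = contacts$pointer_id,
               x = contacts$x, y = contacts$y, phase = "ended"))
  ev <- ev[order(ev$time_s, ev$pointer_id), , drop = FALSE]
  rownames(ev) <- NULL
  ev$time_s <- round(ev$time_s, 2)
  ev
}

#' Generate one complete synthetic session
#'
#' Produces a full 18-trial session for one participant: 6 blocks in which
#' every finger taps once (order randomised within block), 30 s tapping +
#' 30 s rest per trial with the break extended by 30 s after blocks 2 and 4,
#' and optional injected quality violations. The generative ground truth
#' (profile parameters and injected violations) is carried in the session's
#' `truth` element.
#'
#' @param profile a [tapper_profile()].
#' @param seed integer seed; the session is fully reproducible from
#'   `(profile, seed, violations)`.
#' @param violations a list of [violation_spec()] objects; each is applied
#'   to the trials in its `trial_indices`.
#' @param cfg [qc_config()] used to validate injection magnitudes.
#' @return a `tap_session` object; see [read_session()] for the fields.
#' @export
generate_session <- function(profile, seed = 1L, violations = list(),
                             cfg = qc_config()) {
  set.seed(seed)
  finger_order <- as.vector(vapply(1:6, function(b) sample(FINGERS_TAPPING),
                                   character(3)))
  schedule <- trial_schedule(finger_order)
  inj_by_trial <- vector("list", 18L)
  for (v in violations) {
    for (k in v$trial_indices) inj_by_trial[[k]] <- c(inj_by_trial[[k]], list(v))
  }
  inj_log <- list()
  trials <- lapply(1:18, function(k) {
    tr <- build_tap_trial(profile, schedule$finger[k], schedule[k, ])
    for (v in inj_by_trial[[k]]) {
      tr <- inject_violation(tr, v, rng_seed = sample.int(2^31 - 1L, 1L),
                             cfg = cfg)
      inj_log[[length(inj_log) + 1L]] <<- data.frame(
        trial_index = k, criterion = v$criterion, magnitude = v$magnitude)
    }
    tr
  })
  injections <- if (length(inj_log)) do.call(rbind, inj_log) else
    data.frame(trial_index = integer(0), criterion = integer(0),
               magnitude = numeric(0))
  assemble_session(profile, trials, schedule, injections)
}

#' @export
print.tap_session <- function(x, ...) {
  p <- x$participant
  cat(sprintf("<tap_session> %s (%s, %s, %d y): %d trials, %d touch events, %d accel samples\n",
              p$participant_id, p$age_group, p$sex, p$age_years,
              nrow(x$trials), nrow(x$touches), nrow(x$accel)))
  if (!is.null(x$truth) && nrow(x$truth$injections)) {
    cat(sprintf("  injected violations: %s\n",
                paste(sprintf("trial %d (criterion %d)",
                              x$truth$injections$trial_index,
                              x$truth$injections$criterion), collapse = ", ")))
  }
  invisible(x)
}

#' Generate a synthetic cohort of tapping sessions
#'
#' Samples participant profiles from the distributions in a
#' [cohort_config()] and generates one full session per participant, with
#' quality violations injected at the configured per-trial rate. The whole
#' cohort is reproducible from `config$seed`, and every session carries its
#' generative ground truth for downstream validation.
#'
#' @param config a [cohort_config()].
#' @return a list of `tap_session` objects (class `tap_cohort`), with the
#'   config attached as attribute `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_young + config$n_aged
  groups <- rep(c("young", "aged"), c(config$n_young, config$n_aged))
  sessions <- vector("list", n)
  for (i in seq_len(n)) {
    g <- groups[i]
    sex <- if (stats::runif(1) < config$fraction_female) "female" else "male"
    hand <- if (stats::runif(1) < config$fraction_left_handed) "left" else "right"
    age <- if (g == "young") sample(18:30, 1L) else sample(50:70, 1L)
    u <- stats::rnorm(1L, 0, config$f0_sd)
    f0 <- config$f0_mean[[g]][FINGERS_TAPPING] + u +
      stats::rnorm(3L, 0, 0.1) +
      if (sex == "male") config$sex_effect_hz else 0
    f0 <- pmax(f0, 3)
    base_d <- stats::rnorm(1L, config$decrease_mean[[g]],
                           config$decrease_sd[[g]])
    d <- base_d + c(index = -0.02, middle = 0, little = 0.02)
    d <- pmin(pmax(d, config$decrease_range[1L]), config$decrease_range[2L])
    tau <- min(max(stats::rnorm(1L, config$tau_mean, config$tau_sd), 10), 60)
    profile <- tapper_profile(
      participant_id = sprintf("%s%03d", substr(g, 1, 1), i),
      age_years = age, age_group = g, sex = sex, handedness = hand,
      f0 = f0, decrease = d, tau = tau, iti_cv = config$iti_cv)
    violations <- list()
    if (config$violation_rate > 0) {
      hit <- which(stats::runif(18L) < config$violation_rate)
      for (k in hit) {
        crit <- if (length(config$violation_criteria) == 1L)
          config$violation_criteria else sample(config$violation_criteria, 1L)
        violations[[length(violations) + 1L]] <- violation_spec(
          crit, k, default_violation_magnitude(crit))
      }
    }
    sessions[[i]] <- generate_session(
      profile, seed = sample.int(2^31 - 1L, 1L), violations = violations)
  }
  structure(sessions, class = "tap_cohort", config = config)
}
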