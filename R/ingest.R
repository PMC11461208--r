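#' Read a session directory
#'
#' Parses one participant's raw recording from the documented CSV layout:
#' `participant.csv` (metadata), `trials.csv` (the 18-trial schedule),
#' `touch_events.csv` (50 Hz touch stream: `time_s`, `pointer_id`, `x`, `y`,
#' `phase` in began/moved/ended), `accel.csv` (`time_s`, `ax`, `ay`, `az`)
#' and, when present, `truth.json` (generator ground truth). All structural
#' invariants are validated: 18 trial windows with each finger once per
#' block, 30 s tap windows, per-pointer phase sequences
#' `began -> moved* -> ended`, and strictly increasing accelerometer time.
#'
#' @param path directory containing the session files.
#' @return a `tap_session` object.
#' @seealso [write_session()] for the inverse; the two round-trip.
#' @export
read_session <- function(path) {
  need <- c("participant.csv", "trials.csv", "touch_events.csv", "accel.csv")
  for (f in need) {
    if (!file.exists(file.path(path, f))) {
      stop_format(f, "missing from session directory '%s'", path)
    }
  }
  read1 <- function(f, cols) {
    d <- utils::read.csv(file.path(path, f), stringsAsFactors = FALSE)
    miss <- setdiff(cols, names(d))
    if (length(miss)) {
      stop_format(f, "missing column(s): %s", paste(miss, collapse = ", "))
    }
    d
  }
  participant <- read1("participant.csv",
                       c("participant_id", "age_years", "age_group", "sex",
                         "handedness"))
  trials <- read1("trials.csv",
                  c("trial_index", "block", "finger", "cue_time_s",
                    "tap_start_s", "tap_end_s", "rest_end_s"))
  touches <- read1("touch_events.csv",
                   c("time_s", "pointer_id", "x", "y", "phase"))
  accel <- read1("accel.csv", c("time_s", "ax", "ay", "az"))
  truth_file <- file.path(path, "truth.json")
  truth <- if (file.exists(truth_file)) {
    jsonlite::fromJSON(truth_file, simplifyVector = TRUE)
  }
  validate_session(participant, trials, touches, accel)
  if (!is.null(truth)) {
    truth$injections <- as.data.frame(truth$injections)
    truth$profile$f0 <- unlist(truth$profile$f0)
    truth$profile$decrease <- unlist(truth$profile$decrease)
  }
  structure(list(participant = participant, trials = trials,
                 touches = touches, accel = accel, truth = truth),
            class = "tap_session")
}

validate_session <- function(participant, trials, touches, accel) {
  if (nrow(participant) != 1L) {
    stop_format("participant.csv", "expected exactly 1 row, found %d",
                nrow(participant))
  }
  if (nrow(trials) != 18L) {
    stop_format("trials.csv", "expected 18 trial windows, found %d",
                nrow(trials))
  }
  trials <- trials[order(trials$trial_index), ]
  for (b in unique(trials$block)) {
    fset <- trials$finger[trials$block == b]
    if (!setequal(fset, FINGERS_TAPPING) || length(fset) != 3L) {
      stop_format("trials.csv",
                  "block %s must contain each tapping finger exactly once", b)
    }
  }
  bad <- which(!(trials$cue_time_s <= trials$tap_start_s &
                   trials$tap_start_s < trials$tap_end_s &
                   trials$tap_end_s <= trials$rest_end_s))
  if (length(bad)) {
    stop_format("trials.csv", "row %d: inconsistent window times", bad[1L])
  }
  bad <- which(abs(trials$tap_end_s - trials$tap_start_s - 30) > 1e-9)
  if (length(bad)) {
    stop_format("trials.csv", "row %d: tap window must last 30 s", bad[1L])
  }
  if (nrow(touches) == 0L) {
    stop_format("touch_events.csv", "no touch events (empty stream)")
  }
  if (any(touches$time_s < 0)) {
    stop_format("touch_events.csv", "row %d: negative time",
                which(touches$time_s < 0)[1L])
  }
  if (!all(touches$phase %in% c("began", "moved", "ended"))) {
    stop_format("touch_events.csv", "row %d: unknown phase '%s'",
                which(!touches$phase %in% c("began", "moved", "ended"))[1L],
                touches$phase[!touches$phase %in%
                                c("began", "moved", "ended")][1L])
  }
  ord <- order(touches$pointer_id, touches$time_s)
  for (grp in split(ord, touches$pointer_id[ord])) {
    ph <- touches$phase[grp]
    ok <- ph[1L] == "began" && ph[length(ph)] == "ended" &&
      all(ph[-c(1L, length(ph))] == "moved")
    if (!ok) {
      stop_format("touch_events.csv",
                  "pointer %s: phase sequence is not began -> moved* -> ended",
                  touches$pointer_id[grp[1L]])
    }
  }
  if (nrow(accel) && any(diff(accel$time_s) <= 0)) {
    stop_format("accel.csv", "row %d: time not strictly increasing",
                which(diff(accel$time_s) <= 0)[1L] + 1L)
  }
  invisible(TRUE)
}

#' Write a session to a directory
#'
#' Inverse of [read_session()]: emits the same CSV layout (plus
#' `truth.json` when the session carries generator ground truth), so that
#' `read_session(write_session(s, d))` reproduces `s` content-wise.
#'
#' @param session a `tap_session`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "tap_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  wr <- function(d, f) utils::write.csv(d, file.path(path, f),
                                        row.names = FALSE, quote = FALSE)
  wr(session$participant, "participant.csv")
  wr(session$trials, "trials.csv")
  wr(session$touches, "touch_events.csv")
  wr(session$accel, "accel.csv")
  if (!is.null(session$truth)) {
    jsonlite::write_json(session$truth, file.path(path, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# Collapse the touch event stream into one row per contact.
touch_contacts <- function(touches) {
  o <- order(touches$pointer_id, touches$time_s)
  t <- touches[o, ]
  began <- t[t$phase == "began", ]
  ended <- t[t$phase == "ended", ]
  began <- began[match(ended$pointer_id, began$pointer_id), ]
  data.frame(pointer_id = began$pointer_id,
             t_began = began$time_s, t_ended = ended$time_s,
             x = began$x, y = began$y)
}

#' Assign touch contacts to anatomical fingers
#'
#' Labels every screen contact as index, middle, ring or little finger from
#' its x-coordinate. Home positions are established from the earliest
#' simultaneous resting contacts, ranked by x: ascending x maps to
#' index..little for a right hand and is mirrored for a left hand. Every
#' later contact is claimed by the nearest home position; if homes cannot be
#' established (fewer than four initial touches) the available contacts are
#' labelled by x-rank.
#'
#' @param session a `tap_session`.
#' @return a `finger_tracks` data.frame: one row per contact with columns
#'   `pointer_id`, `finger`, `t_began`, `t_ended`, `x`, `y`. More than four
#'   simultaneous non-thumb touches are flagged in attribute
#'   `compliance_flag` (routed to the quality check), never an error.
#' @export
assign_fingers <- function(session) {
  stopifnot(inherits(session, "tap_session"))
  contacts <- touch_contacts(session$touches)
  contacts <- contacts[order(contacts$t_began, contacts$x), ]
  hand <- session$participant$handedness
  rank_names <- if (hand == "left") rev(FINGERS_ALL) else FINGERS_ALL

  # Home positions: contacts active at the time the 4th earliest contact
  # begins (the initial resting placement); fall back to x-rank of whatever
  # is on screen first.
  t4 <- if (nrow(contacts) >= 4L) contacts$t_began[4L] else
    contacts$t_began[nrow(contacts)]
  init <- contacts[contacts$t_began <= t4 & contacts$t_ended > t4, ]
  if (nrow(init) < 2L) init <- utils::head(contacts, 4L)
  init <- init[order(init$x), ]
  homes <- stats::setNames(init$x, rank_names[seq_len(min(nrow(init), 4L))])

  nearest <- vapply(contacts$x, function(x) {
    names(homes)[which.min(abs(homes - x))]
  }, character(1L))
  contacts$finger <- nearest
  contacts <- contacts[, c("pointer_id", "finger", "t_began", "t_ended",
                           "x", "y")]
  overlap <- max_simultaneous(contacts$t_began, contacts$t_ended)
  structure(contacts, class = c("finger_tracks", "data.frame"),
            compliance_flag = overlap > 4L)
}

max_simultaneous <- function(starts, ends) {
  ev <- c(starts, ends)
  d <- c(rep(1L, length(starts)), rep(-1L, length(ends)))
  o <- order(ev, -d)
  max(cumsum(d[o]))
}

#' Extract the tap series of one trial
#'
#' Collects the `began` events of the instructed finger inside the half-open
#' tap window `[cue, tap_end)` and their successive differences (inter-tap
#' intervals). Touches beginning in the window from any other finger with a
#' transient contact (shorter than `tap_max_contact_s`) are recorded as
#' wrong-finger events for the finger-compliance criterion; long contacts
#' (resting placements) are not taps.
#'
#' @param tracks a `finger_tracks` data.frame from [assign_fingers()].
#' @param window one row of the trial schedule.
#' @param tap_max_contact_s longest contact still counted as a tap, seconds.
#' @return a `tap_series`: list with `tap_times_s`, `itis_s`,
#'   `wrong_finger_times_s`, and the window metadata. Zero taps give an
#'   empty series, not an error.
#' @export
detect_taps <- function(tracks, window, tap_max_contact_s = 1) {
  stopifnot(inherits(tracks, "finger_tracks"))
  in_win <- tracks$t_began >= window$cue_time_s &
    tracks$t_began < window$tap_end_s
  own <- in_win & tracks$finger == window$finger
  wrong <- in_win & tracks$finger != window$finger &
    (tracks$t_ended - tracks$t_began) <= tap_max_contact_s
  tap_times <- sort(tracks$t_began[own])
  structure(list(tap_times_s = tap_times,
                 itis_s = diff(tap_times),
                 wrong_finger_times_s = sort(tracks$t_began[wrong]),
                 trial_index = window$trial_index,
                 finger = window$finger,
                 cue_time_s = window$cue_time_s,
                 tap_start_s = window$tap_start_s,
                 tap_end_s = window$tap_end_s),
            class = "tap_series")
}

#' @export
print.tap_series <- function(x, ...) {
  cat(sprintf("<tap_series> trial %s (%s): %d taps", x$trial_index,
              x$finger, length(x$tap_times_s)))
  if (length(x$itis_s)) {
    cat(sprintf(", median ITI %.3f s (%.1f Hz)", stats::median(x$itis_s),
                1 / stats::median(x$itis_s)))
  }
  if (length(x$wrong_finger_times_s)) {
    cat(sprintf(", %d wrong-finger taps", length(x$wrong_finger_times_s)))
  }
  cat("\n")
  invisible(x)
}
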