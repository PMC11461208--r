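#' Tapper profile: generative parameters for one participant
#'
#' Bundles the parameters that govern a synthetic participant's tapping
#' behaviour: initial (maximal) tapping speed per finger, the fraction of
#' speed lost over a 30 s trial, the time constant of the slowing ramp, and
#' the coefficient of variation of inter-tap intervals.
#'
#' @param participant_id character scalar.
#' @param age_years integer age; must be consistent with `age_group`
#'   (18-30 for "young", 50-70 for "aged").
#' @param age_group `"young"` or `"aged"`.
#' @param sex `"male"` or `"female"`.
#' @param handedness `"left"` or `"right"`.
#' @param f0 named numeric vector of initial tapping speeds in Hz, one per
#'   tapping finger (`index`, `middle`, `little`); all positive.
#' @param decrease named numeric vector (same names) of fractional speed loss
#'   over the trial, each in `[0, 1)`.
#' @param tau slowing time constant in seconds (> 0); larger values give a
#'   more linear, less saturating ramp.
#' @param iti_cv coefficient of variation of the multiplicative inter-tap
#'   interval jitter (>= 0).
#' @return an object of class `tapper_profile`.
#' @examples
#' p <- tapper_profile("p01", age_years = 25, age_group = "young",
#'                     sex = "female", handedness = "right")
#' p$f0
#' @export
tapper_profile <- function(participant_id,
                           age_years,
                           age_group = c("young", "aged"),
                           sex = c("male", "female"),
                           handedness = c("right", "left"),
                           f0 = c(index = 6.0, middle = 5.7, little = 5.1),
                           decrease = c(index = 0.14, middle = 0.17,
                                        little = 0.20),
                           tau = 30,
                           iti_cv = 0.02) {
  age_group <- match.arg(age_group)
  sex <- match.arg(sex)
  handedness <- match.arg(handedness)
  age_years <- as.integer(age_years)
  rng <- if (age_group == "young") c(18L, 30L) else c(50L, 70L)
  if (age_years < rng[1] || age_years > rng[2]) {
    stop_param("age_years = %d is inconsistent with age_group '%s' (%d-%d)",
               age_years, age_group, rng[1], rng[2])
  }
  f0 <- f0[FINGERS_TAPPING]
  decrease <- decrease[FINGERS_TAPPING]
  if (anyNA(f0) || any(f0 <= 0)) {
    stop_param("f0 must be positive for fingers %s",
               paste(FINGERS_TAPPING, collapse = ", "))
  }
  if (anyNA(decrease) || any(decrease < 0) || any(decrease >= 1)) {
    stop_param("decrease must lie in [0, 1) for every finger")
  }
  if (!is.numeric(tau) || tau <= 0) stop_param("tau must be > 0")
  if (!is.numeric(iti_cv) || iti_cv < 0) stop_param("iti_cv must be >= 0")
  structure(
    list(participant_id = as.character(participant_id),
         age_years = age_years, age_group = age_group, sex = sex,
         handedness = handedness, f0 = f0, decrease = decrease,
         tau = tau, iti_cv = iti_cv),
    class = "tapper_profile")
}

#' @export
print.tapper_profile <- function(x, ...) {
  cat(sprintf("<tapper_profile> %s: %s, %s, %d y, %s-handed\n",
              x$participant_id, x$age_group, x$sex, x$age_years,
              x$handedness))
  cat(sprintf("  f0 [Hz]: %s\n",
              paste(sprintf("%s=%.2f", names(x$f0), x$f0), collapse = " ")))
  cat(sprintf("  decrease: %s  tau=%.1fs  iti_cv=%.3f\n",
              paste(sprintf("%s=%.2f", names(x$decrease), x$decrease),
                    collapse = " "),
              x$tau, x$iti_cv))
  invisible(x)
}

#' Specification of an injected quality-control violation
#'
#' Describes which trials of a synthetic session should be corrupted so that
#' they unambiguously fail one specific quality criterion. The meaning of
#' `magnitude` depends on the criterion:
#' \describe{
#'   \item{1}{smoothed accelerometer z amplitude (device units, must exceed
#'     the 0.4 threshold)}
#'   \item{2}{start latency in seconds (must exceed 1.5 s; at most 4 s so
#'     the speed-profile checks are untouched)}
#'   \item{3}{number of wrong-finger taps (>= 1)}
#'   \item{4}{time of the frequency maximum in seconds (> 10 s after trial
#'     start)}
#'   \item{5}{time of the frequency minimum in seconds (before the last
#'     10 s; 5-18 s after trial start)}
#'   \item{6}{number of taps during the rest period (>= 1)}
#'   \item{7}{gap length in seconds (> 2 s; a single gap if > 5 s, otherwise
#'     four repeated gaps to exceed the allowed count)}
#' }
#'
#' @param criterion integer 1-7.
#' @param trial_indices integer vector of trial indices (1-18) to corrupt.
#' @param magnitude criterion-specific scalar, see Details; validated to be
#'   strictly beyond the corresponding quality threshold.
#' @param cfg a [qc_config()] supplying the thresholds used for validation.
#' @return an object of class `violation_spec`.
#' @export
violation_spec <- function(criterion, trial_indices, magnitude,
                           cfg = qc_config()) {
  criterion <- as.integer(criterion)
  if (length(criterion) != 1L || is.na(criterion) ||
      criterion < 1L || criterion > 7L) {
    stop_param("criterion must be a single integer in 1..7")
  }
  trial_indices <- as.integer(trial_indices)
  if (length(trial_indices) < 1L || anyNA(trial_indices) ||
      any(trial_indices < 1L | trial_indices > 18L)) {
    stop_param("trial_indices must be integers in 1..18")
  }
  ok <- switch(criterion,
    magnitude > cfg$accel_thresholds[["z"]],                      # 1
    magnitude > cfg$start_latency_max_s && magnitude <= 4,        # 2
    magnitude >= 1,                                               # 3
    magnitude > cfg$early_max_window_s && magnitude < 28,         # 4
    magnitude > 5 && magnitude <= 18,                             # 5
    magnitude >= 1 && magnitude <= 8,                             # 6
    magnitude > cfg$iti_gap_s)                                    # 7
  if (!isTRUE(ok)) {
    stop_param(paste0("magnitude %.3g is not strictly beyond the threshold ",
                      "for criterion %d (injected trials must be ",
                      "unambiguously invalid)"), magnitude, criterion)
  }
  structure(list(criterion = criterion,
                 trial_indices = sort(unique(trial_indices)),
                 magnitude = magnitude),
            class = "violation_spec")
}

#' Cohort configuration for the synthetic session generator
#'
#' Distributions from which participant profiles are sampled, plus the
#' per-trial probability that a quality violation is injected. Defaults
#' emulate a field study of healthy adults: young participants tap faster
#' than aged ones (most clearly with the index and middle fingers), males
#' slightly faster than females, and every trial slows by roughly 17% from
#' its maximal to its minimal speed.
#'
#' @param n_young,n_aged numbers of participants per age group.
#' @param seed integer seed controlling all sampling.
#' @param violation_rate probability (per trial) that one of the seven
#'   quality violations is injected; the violated criterion is drawn
#'   uniformly from `violation_criteria`.
#' @param violation_criteria integer vector, the criteria eligible for
#'   injection.
#' @param f0_mean named list `young`/`aged`, each a named vector of mean
#'   initial speeds (Hz) per finger for female participants; `sex_effect_hz`
#'   is added for males.
#' @param f0_sd between-participant standard deviation of initial speed (Hz).
#' @param sex_effect_hz additive male-female difference in initial speed (Hz).
#' @param decrease_mean,decrease_sd named vectors (`young`, `aged`) giving
#'   the mean and SD of the fractional speed decrease.
#' @param decrease_range decreases are resampled into this range so that
#'   nominally clean trials keep a clear margin to the speed-profile quality
#'   criteria (see the package vignette).
#' @param tau_mean,tau_sd slowing ramp time constant distribution (s).
#' @param iti_cv inter-tap-interval coefficient of variation.
#' @param fraction_female,fraction_left_handed cohort composition.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_young = 10, n_aged = 10, seed = 1L,
                          violation_rate = 0,
                          violation_criteria = 1:7,
                          f0_mean = list(
                            young = c(index = 6.4, middle = 6.0,
                                      little = 5.3),
                            aged = c(index = 5.8, middle = 5.5,
                                     little = 5.05)),
                          f0_sd = 0.45,
                          sex_effect_hz = 0.3,
                          decrease_mean = c(young = 0.170, aged = 0.165),
                          decrease_sd = c(young = 0.03, aged = 0.03),
                          decrease_range = c(0.12, 0.28),
                          tau_mean = 30, tau_sd = 6,
                          iti_cv = 0.02,
                          fraction_female = 0.5,
                          fraction_left_handed = 0.08) {
  if (n_young < 0 || n_aged < 0) stop_param("participant counts must be >= 0")
  if (violation_rate < 0 || violation_rate > 1) {
    stop_param("violation_rate must lie in [0, 1]")
  }
  if (f0_sd < 0 || tau_sd < 0 || any(decrease_sd < 0)) {
    stop_param("all standard deviations must be >= 0")
  }
  if (iti_cv < 0) stop_param("iti_cv must be >= 0")
  structure(
    list(n_young = as.integer(n_young), n_aged = as.integer(n_aged),
         seed = as.integer(seed), violation_rate = violation_rate,
         violation_criteria = as.integer(violation_criteria),
         f0_mean = f0_mean, f0_sd = f0_sd, sex_effect_hz = sex_effect_hz,
         decrease_mean = decrease_mean, decrease_sd = decrease_sd,
         decrease_range = decrease_range,
         tau_mean = tau_mean, tau_sd = tau_sd, iti_cv = iti_cv,
         fraction_female = fraction_female,
         fraction_left_handed = fraction_left_handed),
    class = "cohort_config")
}
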