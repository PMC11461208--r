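# Internal helpers shared across modules.

FRAME_DT <- 0.02  # 50 Hz touch/accelerometer frame period, seconds

FINGERS_TAPPING <- c("index", "middle", "little")
FINGERS_ALL <- c("index", "middle", "ring", "little")

# Home x-coordinates (normalised screen units) for a right hand, palm down.
# Left hands are mirrored (x -> 1 - x).
HOME_X_RIGHT <- c(index = 0.35, middle = 0.50, ring = 0.65, little = 0.80)

snap_frame <- function(t, dt = FRAME_DT) round(t / dt) * dt

frame_grid <- function(from, to, dt = FRAME_DT) {
  # frame-aligned sample times in [from, to)
  i0 <- ceiling(round(from / dt, 6))
  i1 <- ceiling(round(to / dt, 6)) - 1L
  if (i1 < i0) return(numeric(0))
  seq(i0, i1) * dt
}

#' Centred moving average with truncated edges
#'
#' Running mean over a window of `k` samples centred on each point; at the
#' series edges the window is truncated to the available samples (no padding).
#' Used by the device-motion quality check to smooth raw accelerometer traces.
#'
#' @param x numeric vector.
#' @param k odd integer window length in samples.
#' @return numeric vector of the same length as `x`.
#' @keywords internal
moving_average <- function(x, k) {
  n <- length(x)
  if (n == 0L) return(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Cumulative time within [w_lo, w_hi) during which fewer than `min_k` of the
# given contact intervals are simultaneously active.  `starts`/`ends` are
# contact onset/offset times.
time_below_count <- function(starts, ends, w_lo, w_hi, min_k) {
  if (w_hi <= w_lo) return(0)
  keep <- ends > w_lo & starts < w_hi
  starts <- pmax(starts[keep], w_lo)
  ends <- pmin(ends[keep], w_hi)
  ev_t <- c(w_lo, starts, ends, w_hi)
  ev_d <- c(0, rep(1L, length(starts)), rep(-1L, length(ends)), 0L)
  o <- order(ev_t, -ev_d)  # starts before ends at ties: touching contacts overlap
  ev_t <- ev_t[o]
  ev_d <- cumsum(ev_d[o])
  dt <- diff(ev_t)
  sum(dt[ev_d[-length(ev_d)] < min_k])
}

match_arg_chr <- function(x, choices, what) {
  if (length(x) != 1L || !x %in% choices) {
    stop(sprintf("`%s` must be one of %s", what,
                 paste(sQuote(choices), collapse = ", ")), call. = FALSE)
  }
  x
}

stop_param <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

stop_format <- function(file, fmt, ...) {
  stop(sprintf("[%s] %s", file, sprintf(fmt, ...)), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
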