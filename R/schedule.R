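#' Define a light-dark schedule
#'
#' A light schedule describes the zeitgeber regime a culture experienced:
#' the cycle length, the light fraction of each cycle, when the first light
#' onset occurred, an optional transfer into constant darkness (DD), and any
#' abrupt schedule shifts ("jet-lag" events, e.g. an 8 h delay of the
#' light-dark cycle).
#'
#' @param cycle_length Length of one zeitgeber cycle in hours. Default 24.
#' @param light_fraction Fraction of the cycle that is lit, strictly between
#'   0 and 1. Default 0.5 (a 12:12 LD cycle).
#' @param phase_offset Time (h) of the first light onset relative to the
#'   start of the experiment. Default 0.
#' @param dd_start Time (h) of transfer into constant darkness, or `NULL`
#'   if the culture stays under LD cycles throughout.
#' @param shift_events A data frame with columns `time` (h) and `delay`
#'   (signed h, positive = the schedule is delayed) describing abrupt
#'   schedule shifts, ordered by time. Default: none.
#'
#' @return An object of class `light_schedule`.
#' @examples
#' light_schedule()                                   # 12:12 LD
#' light_schedule(dd_start = 48)                      # LD then DD at 48 h
#' light_schedule(shift_events = data.frame(time = 96, delay = 8))
#' @export
light_schedule <- function(cycle_length = 24, light_fraction = 0.5,
                           phase_offset = 0, dd_start = NULL,
                           shift_events = NULL) {
  stopifnot(is.numeric(cycle_length), length(cycle_length) == 1,
            cycle_length > 0)
  stopifnot(is.numeric(light_fraction), length(light_fraction) == 1,
            light_fraction > 0, light_fraction < 1)
  if (!is.null(dd_start)) {
    stopifnot(is.numeric(dd_start), length(dd_start) == 1, dd_start >= 0)
  }
  if (is.null(shift_events)) {
    shift_events <- tibble::tibble(time = numeric(), delay = numeric())
  } else {
    shift_events <- tibble::as_tibble(shift_events)
    stopifnot(all(c("time", "delay") %in% names(shift_events)))
    shift_events <- shift_events[c("time", "delay")]
    if (nrow(shift_events) > 1 && any(diff(shift_events$time) <= 0)) {
      stop("shift_events must be strictly increasing in time")
    }
  }
  structure(
    list(cycle_length = cycle_length, light_fraction = light_fraction,
         phase_offset = phase_offset, dd_start = dd_start,
         shift_events = shift_events),
    class = "light_schedule"
  )
}

#' @export
print.light_schedule <- function(x, ...) {
  lf <- x$light_fraction * x$cycle_length
  cat(sprintf("<light_schedule> %g:%g LD, cycle %g h, first light onset %g h\n",
              lf, x$cycle_length - lf, x$cycle_length, x$phase_offset))
  if (!is.null(x$dd_start)) cat(sprintf("  transfer to DD at %g h\n", x$dd_start))
  if (nrow(x$shift_events)) {
    cat(sprintf("  %d shift event(s): %s\n", nrow(x$shift_events),
                paste(sprintf("%+g h at %g h", x$shift_events$delay,
                              x$shift_events$time), collapse = ", ")))
  }
  invisible(x)
}

#' Define circadian clock parameters
#'
#' Parameters of the endogenous oscillator driving ring deposition: its
#' free-running period (FRP) under constant darkness, the phase of ring
#' deposition relative to dark onset while entrained, and the time constant
#' with which the realized phase relaxes onto a shifted schedule.
#'
#' @param free_running_period FRP in hours under constant conditions.
#'   Default 24.5.
#' @param entrained_phase Ring-deposition phase (h) relative to dark onset
#'   under entrainment. Default 0 (deposition at dark onset).
#' @param relaxation_tau Exponential time constant (h) of phase
#'   re-entrainment after a schedule shift; 0 means instantaneous
#'   re-entrainment. Default 36.
#'
#' @return An object of class `clock_params`.
#' @export
clock_params <- function(free_running_period = 24.5, entrained_phase = 0,
                         relaxation_tau = 36) {
  stopifnot(is.numeric(free_running_period), free_running_period > 0)
  stopifnot(is.numeric(relaxation_tau), relaxation_tau >= 0)
  structure(
    list(free_running_period = free_running_period,
         entrained_phase = entrained_phase,
         relaxation_tau = relaxation_tau),
    class = "clock_params"
  )
}

#' @export
print.clock_params <- function(x, ...) {
  cat(sprintf(
    "<clock_params> FRP %g h, deposition %+g h from dark onset, tau %g h\n",
    x$free_running_period, x$entrained_phase, x$relaxation_tau))
  invisible(x)
}

# Light on/off toggle times over [0, t_max], honouring shift events and DD.
# Returns a tibble with columns onset, offset (h); rows may be truncated by
# dd_start. Used for actogram light marks.
light_intervals <- function(schedule, t_max) {
  cl <- schedule$cycle_length
  lit <- schedule$light_fraction * cl
  ev <- schedule$shift_events
  onsets <- numeric()
  t_on <- schedule$phase_offset
  applied <- rep(FALSE, nrow(ev))
  while (t_on <= t_max + cl) {
    onsets <- c(onsets, t_on)
    t_next <- t_on + cl
    # a shift event between this onset and the next delays all later toggles
    hit <- which(!applied & ev$time > t_on & ev$time <= t_next)
    if (length(hit)) {
      t_next <- t_next + sum(ev$delay[hit])
      applied[hit] <- TRUE
    }
    t_on <- t_next
  }
  out <- tibble::tibble(onset = onsets, offset = onsets + lit)
  if (!is.null(schedule$dd_start)) {
    out <- out[out$onset < schedule$dd_start, , drop = FALSE]
    out$offset <- pmin(out$offset, schedule$dd_start)
  }
  out[out$onset < t_max & out$offset > 0, , drop = FALSE]
}
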