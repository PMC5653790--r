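#' @keywords internal
#' @noRd
# Realized oscillator phase in cycles at times t (vectorized, analytic).
#
# Under entrainment the phase tracks the schedule: it advances at
# 1/cycle_length and a schedule delay d moves the entrainment target back by
# d/cycle_length; the realized phase stays continuous and relaxes onto the
# new target exponentially with time constant tau (tau = 0: instantaneous).
# From dd_start onward the oscillator free-runs at 1/free_running_period
# from whatever phase it had reached.
phase_cycles_at <- function(schedule, clock, t) {
  cl <- schedule$cycle_length
  tau <- clock$relaxation_tau
  ev <- schedule$shift_events
  dd <- schedule$dd_start
  if (!is.null(dd) && nrow(ev) && any(ev$time >= dd)) {
    warning("shift events at or after dd_start are ignored (no light in DD)")
    ev <- ev[ev$time < dd, , drop = FALSE]
  }
  entrained <- function(tt) {
    phi <- (tt - schedule$phase_offset) / cl
    if (nrow(ev)) {
      for (i in seq_len(nrow(ev))) {
        past <- tt >= ev$time[i]
        d <- ev$delay[i] / cl
        phi[past] <- phi[past] - d
        if (tau > 0) {
          phi[past] <- phi[past] + d * exp(-(tt[past] - ev$time[i]) / tau)
        }
      }
    }
    phi
  }
  if (is.null(dd)) return(entrained(t))
  phi <- entrained(pmin(t, dd))
  free <- t > dd
  phi[free] <- phi[free] + (t[free] - dd) / clock$free_running_period
  phi
}

# Phase value (in cycles, modulo 1) at which a ring is deposited:
# dark onset plus the entrained_phase offset.
deposition_level <- function(schedule, clock) {
  (schedule$light_fraction * schedule$cycle_length + clock$entrained_phase) /
    schedule$cycle_length
}

#' Sample the realized clock-phase trajectory
#'
#' Integrates the phase model over a light schedule: the phase advances at
#' one cycle per zeitgeber cycle while entrained and at one cycle per
#' free-running period after transfer to constant darkness; after an abrupt
#' schedule shift the realized phase relaxes exponentially (time constant
#' `relaxation_tau`) onto the shifted schedule, staying continuous in time.
#'
#' @param schedule A [light_schedule()].
#' @param clock A [clock_params()].
#' @param duration Total duration (h) to sample.
#' @param dt Sampling step (h); must be positive.
#'
#' @return A tibble with columns `time_h` and `phase_h` (subjective hours,
#'   i.e. phase in cycles times the cycle length), plus attribute
#'   `phase_cycles`.
#' @examples
#' tr <- clock_phase_trajectory(light_schedule(), clock_params(), 144, 0.5)
#' @export
clock_phase_trajectory <- function(schedule, clock, duration, dt = 0.1) {
  stopifnot(inherits(schedule, "light_schedule"), inherits(clock, "clock_params"))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  if (duration < dt) stop("duration must be at least dt")
  ev <- schedule$shift_events
  if (nrow(ev) && any(ev$time > duration)) {
    warning("shift events after the end of the record have no effect")
  }
  t <- sort(unique(c(seq(0, duration, by = dt), duration,
                     schedule$dd_start, ev$time[ev$time <= duration])))
  phi <- phase_cycles_at(schedule, clock, t)
  out <- tibble::tibble(time_h = t, phase_h = phi * schedule$cycle_length)
  attr(out, "phase_cycles") <- phi
  out
}

#' Ring deposition times implied by a schedule and clock
#'
#' One ring is deposited per full clock cycle, at the moment the realized
#' phase crosses the deposition phase (dark onset plus `entrained_phase`).
#' Under a 24 h LD cycle this yields one ring every 24 h; in constant
#' darkness rings are spaced by the free-running period.
#'
#' @inheritParams clock_phase_trajectory
#' @return Numeric vector of ring times (h), strictly increasing; length 0
#'   (with a message) when the record is shorter than one cycle.
#' @examples
#' ring_deposition_times(light_schedule(), clock_params(), 144)
#' @export
ring_deposition_times <- function(schedule, clock, duration) {
  stopifnot(inherits(schedule, "light_schedule"), inherits(clock, "clock_params"))
  stopifnot(duration > 0)
  p0 <- deposition_level(schedule, clock)
  f <- function(t) phase_cycles_at(schedule, clock, t)
  # dense grid bracketing + root polish; phase is monotone increasing
  grid <- sort(unique(c(seq(0, duration, by = 0.05), duration,
                        schedule$dd_start,
                        schedule$shift_events$time[schedule$shift_events$time <= duration])))
  phi <- f(grid)
  # a ring is deposited at the FIRST upward crossing of each level; with an
  # instantaneous schedule delay the phase steps back, and the running
  # maximum guards against depositing the same ring twice
  m <- cummax(phi)
  ks <- seq(ceiling(min(phi) - p0), floor(max(phi) - p0))
  ks <- ks[p0 + ks > min(phi) & p0 + ks <= max(phi)]
  times <- vapply(ks, function(k) {
    lev <- p0 + k
    i <- findInterval(lev, m)  # last index with running max < lev (+ties)
    if (i < 1 || i >= length(grid)) return(NA_real_)
    if (m[i] == lev) return(grid[i])
    lo <- grid[i]; hi <- grid[i + 1]
    stats::uniroot(function(u) f(u) - lev, c(lo, hi),
                   tol = 1e-10)$root
  }, numeric(1))
  times <- sort(times[!is.na(times) & times > 0 & times <= duration])
  if (!length(times)) message("record shorter than one clock cycle: no rings")
  times
}
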