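#' Build a double-plotted actogram from a calibrated profile
#'
#' Resamples the band-intensity signal onto a uniform time grid and lays it
#' out one row per day, each row spanning `row_hours` (48 h by default, so
#' the right half of each row repeats as the left half of the next: the
#' classic double plot that makes phase drifts visible). Light onset and
#' offset marks are computed from the schedule, including shift events.
#'
#' @param profile A `radial_profile`.
#' @param calibration A [calibrate()] result.
#' @param schedule A [light_schedule()] (used only for the light marks;
#'   pass `NULL` to omit them).
#' @param row_hours Hours per row. Default 48 (double-plotted).
#' @param bin_width Bin width in hours. Default 0.5.
#' @param detrend Quadratically detrend the profile first? Default `TRUE`.
#' @return An object of class `actogram`: a list with `rows` (matrix,
#'   one row per day), `bin_width`, `row_hours`, `day0_time` and
#'   `light_marks` (tibble row, onset, offset within-row hours).
#' @export
build_actogram <- function(profile, calibration, schedule = NULL,
                           row_hours = 48, bin_width = 0.5, detrend = TRUE) {
  stopifnot(inherits(calibration, "time_calibration"))
  if (detrend && !is_detrended(profile)) profile <- detrend_quadratic(profile)
  t <- calibration$pos_to_time(profile$position_px)
  y <- profile$intensity
  o <- order(t)
  t <- t[o]; y <- y[o]
  if (diff(range(t)) < 2 * 24) stop("record must cover at least two days")
  day0 <- 24 * floor(min(t) / 24)
  # one row per day whose first 24 h lie inside the record; the trailing
  # half of the last row may run past the data and is NA-filled there
  n_rows <- ceiling((max(t) - day0 - 24) / 24)
  if (n_rows < 1) stop("record shorter than one actogram row")
  nbin <- round(row_hours / bin_width)
  centers0 <- (seq_len(nbin) - 0.5) * bin_width
  rows <- matrix(NA_real_, n_rows, nbin)
  for (r in seq_len(n_rows)) {
    tc <- day0 + 24 * (r - 1) + centers0
    rows[r, ] <- stats::approx(t, y, xout = tc, rule = 1)$y
  }
  marks <- NULL
  if (!is.null(schedule)) {
    iv <- light_intervals(schedule, max(t))
    marks <- purrr::map_dfr(seq_len(n_rows), function(r) {
      start <- day0 + 24 * (r - 1)
      sel <- iv$offset > start & iv$onset < start + row_hours
      if (!any(sel)) return(NULL)
      tibble::tibble(row = r,
                     onset = pmax(iv$onset[sel] - start, 0),
                     offset = pmin(iv$offset[sel] - start, row_hours))
    })
  }
  structure(list(rows = rows, row_hours = row_hours, bin_width = bin_width,
                 day0_time = day0, light_marks = marks),
            class = "actogram")
}

#' @export
print.actogram <- function(x, ...) {
  cat(sprintf("<actogram> %d rows x %g h (bin %g h), day 0 at %g h\n",
              nrow(x$rows), x$row_hours, x$bin_width, x$day0_time))
  invisible(x)
}

# wrap a signed difference into (-half, half]
wrap_signed <- function(d, period) {
  w <- (d + period / 2) %% period - period / 2
  ifelse(w == -period / 2, period / 2, w)
}

# least-squares cosine phase at fixed period: returns peak time within
# [0, period) and its delta-method uncertainty (h)
fit_cosine_phase <- function(t, y, period) {
  omega <- 2 * pi / period
  fit <- stats::lm(y ~ cos(omega * t) + sin(omega * t))
  cf <- stats::coef(fit)
  A <- cf[2]; B <- cf[3]
  V <- stats::vcov(fit)[2:3, 2:3]
  den <- A^2 + B^2
  # d(atan2(B,A)) = (A dB - B dA) / (A^2 + B^2)
  var_phase <- (A^2 * V[2, 2] + B^2 * V[1, 1] - 2 * A * B * V[1, 2]) / den^2
  peak <- (atan2(B, A) / omega) %% period
  list(peak_time = as.numeric(peak),
       uncertainty = as.numeric(sqrt(pmax(var_phase, 0))) / omega,
       amplitude = sqrt(den))
}

#' Estimate the phase shift around a schedule change
#'
#' Fits the phase of a cosine at a fixed period separately to the segment
#' before the schedule change and to the segment after the change once a
#' re-entrainment transient has been skipped, and reports the circular
#' difference. Positive `delta` means the rhythm was delayed (the jet-lag
#' convention: an 8 h delay of the light cycle yields `delta` near +8).
#'
#' @param profile A `radial_profile`.
#' @param calibration A [calibrate()] result.
#' @param shift_time Time (h) of the schedule change.
#' @param period Period (h) of the fitted cosine (the entraining cycle
#'   length, typically 24).
#' @param skip_transient Hours after `shift_time` excluded from the post
#'   fit while the rhythm re-entrains. Default 72 ("a few days").
#' @param detrend Quadratically detrend first? Default `TRUE`.
#' @return An object of class `phase_shift_estimate` with fields `delta`
#'   (signed h), `pre_phase`, `post_phase` (peak times mod period),
#'   `period_used`, `skipped_transient`, `uncertainty`.
#' @export
estimate_phase_shift <- function(profile, calibration, shift_time,
                                 period = 24, skip_transient = 72,
                                 detrend = TRUE) {
  stopifnot(inherits(calibration, "time_calibration"), skip_transient >= 0)
  if (detrend && !is_detrended(profile)) profile <- detrend_quadratic(profile)
  t <- calibration$pos_to_time(profile$position_px)
  y <- profile$intensity
  pre <- t < shift_time
  post <- t >= shift_time + skip_transient
  if (sum(pre) < 8 || diff(range(t[pre])) < 2 * period) {
    stop("need at least two periods of data before the shift")
  }
  if (sum(post) < 8 || diff(range(t[post])) < 2 * period) {
    stop("need at least two periods of data after the transient")
  }
  f_pre <- fit_cosine_phase(t[pre], y[pre], period)
  f_post <- fit_cosine_phase(t[post], y[post], period)
  # polarity does not matter: both segments share it, so it cancels
  delta <- wrap_signed(f_post$peak_time - f_pre$peak_time, period)
  structure(
    list(delta = delta, pre_phase = f_pre$peak_time,
         post_phase = f_post$peak_time, period_used = period,
         skipped_transient = skip_transient,
         uncertainty = sqrt(f_pre$uncertainty^2 + f_post$uncertainty^2)),
    class = "phase_shift_estimate"
  )
}

#' @export
print.phase_shift_estimate <- function(x, ...) {
  cat(sprintf(
    "<phase_shift_estimate> delta %+.2f h (+/- %.2f h), period %g h, transient %g h skipped\n",
    x$delta, x$uncertainty, x$period_used, x$skipped_transient))
  invisible(x)
}

#' Write an actogram as CSV
#'
#' One row per actogram day; column names give the within-row bin centre
#' in hours.
#'
#' @param acto An [build_actogram()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_actogram_csv <- function(acto, path) {
  centers <- (seq_len(ncol(acto$rows)) - 0.5) * acto$bin_width
  df <- as.data.frame(acto$rows)
  names(df) <- sprintf("h%05.1f", centers)
  utils::write.csv(cbind(row = seq_len(nrow(df)), df), path, row.names = FALSE)
  invisible(path)
}
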