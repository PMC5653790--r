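#' Pixel-to-hour calibration from two anchor events
#'
#' The time scale of a radial profile follows from constant radial growth:
#' dividing the pixel distance between two events of known time (typically
#' the first and the last ring) by the hours elapsed between them gives the
#' pixels-per-hour scale, and with it an affine position/time mapping.
#'
#' @param anchor_a,anchor_b Numeric vectors `c(position, time)` (px, h) of
#'   two distinct anchor events.
#' @return An object of class `time_calibration` with fields `px_per_h`,
#'   `pos_to_time()` and `time_to_pos()`.
#' @examples
#' cal <- calibrate(c(100, 0), c(820, 144))
#' cal$px_per_h            # 5
#' cal$pos_to_time(460)    # 72
#' @export
calibrate <- function(anchor_a, anchor_b) {
  stopifnot(length(anchor_a) == 2, length(anchor_b) == 2)
  dp <- anchor_b[1] - anchor_a[1]
  dt <- anchor_b[2] - anchor_a[2]
  if (dt == 0) stop("anchor times must differ")
  if (dp == 0) stop("anchor positions must differ")
  slope <- dp / dt # signed px per hour
  pos_to_time <- function(pos) anchor_a[2] + (pos - anchor_a[1]) / slope
  time_to_pos <- function(time) anchor_a[1] + (time - anchor_a[2]) * slope
  structure(
    list(px_per_h = abs(slope), slope = slope,
         anchor_a = anchor_a, anchor_b = anchor_b,
         pos_to_time = pos_to_time, time_to_pos = time_to_pos),
    class = "time_calibration"
  )
}

#' @export
print.time_calibration <- function(x, ...) {
  cat(sprintf("<time_calibration> %g px/h (anchors %g px @ %g h, %g px @ %g h)\n",
              x$px_per_h, x$anchor_a[1], x$anchor_a[2],
              x$anchor_b[1], x$anchor_b[2]))
  invisible(x)
}

#' Calibration from generator ground truth
#'
#' Applies the first-ring/last-ring calibration rule to a
#' [synthetic_truth()] object: anchors at the first and last ring
#' (radius, time) pairs.
#'
#' @param truth A `synthetic_truth` with at least two rings.
#' @param origin_px Radius (px) corresponding to profile position 0, i.e.
#'   where the analysed ROI starts. 0 when positions are radii.
#' @return A `time_calibration`; `px_per_h` equals the growth rate exactly.
#' @export
calibrate_from_truth <- function(truth, origin_px = 0) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n <- length(truth$ring_times)
  if (n < 2) stop("need at least two rings to calibrate")
  calibrate(c(truth$ring_radii[1] - origin_px, truth$ring_times[1]),
            c(truth$ring_radii[n] - origin_px, truth$ring_times[n]))
}

#' Remove the best-fitting quadratic trend
#'
#' Subtracts the least-squares quadratic in position from the intensity,
#' leaving the residual orthogonal to 1, x and x^2. This isolates the
#' periodic banding from the slow radial trend (colony aging, residual
#' illumination) before spectral analysis. Idempotent.
#'
#' @param profile A `radial_profile` (>= 8 points).
#' @return The residual profile, flagged as detrended in its provenance.
#' @export
detrend_quadratic <- function(profile) {
  stopifnot(nrow(profile) >= 8)
  x <- profile$position_px
  if (anyDuplicated(x)) stop("positions must be distinct")
  fit <- stats::lm(profile$intensity ~ x + I(x^2))
  out <- profile
  out$intensity <- as.numeric(stats::residuals(fit))
  log_step(out, "detrend_quadratic")
}

is_detrended <- function(profile) {
  "detrend_quadratic" %in% provenance(profile)
}

#' Detect ring bands in a radial profile
#'
#' Finds local maxima of the (polarity-normalized, quadratically detrended)
#' profile whose topographic prominence is at least `prominence_factor`
#' times the profile standard deviation, keeping peaks at least
#' `min_separation` pixels apart (greedy, by decreasing prominence).
#'
#' @param profile A `radial_profile`; detrended internally if not already
#'   (recorded in provenance).
#' @param min_separation Minimum peak separation (px). Default half the
#'   expected ring spacing when `calibration` and `expected_period` are
#'   given, else 10 px.
#' @param prominence_factor Prominence threshold in units of the profile
#'   SD. Default 0.5.
#' @param polarity `"dark"` rings (intensity minima, default) or
#'   `"bright"` rings (maxima).
#' @param calibration Optional [calibrate()] result; adds a `time_h`
#'   column and informs the default separation.
#' @param expected_period Expected period (h) used with `calibration` for
#'   the default `min_separation`.
#' @return A `ring_set` tibble with columns `position_px`, `prominence`
#'   (and `time_h` when calibrated), sorted by position. Zero rows is a
#'   valid result.
#' @export
detect_rings <- function(profile, min_separation = NULL,
                         prominence_factor = 0.5,
                         polarity = c("dark", "bright"),
                         calibration = NULL, expected_period = 24) {
  polarity <- match.arg(polarity)
  if (!is_detrended(profile)) profile <- detrend_quadratic(profile)
  y <- profile$intensity
  if (polarity == "dark") y <- -y
  if (is.null(min_separation)) {
    min_separation <- if (!is.null(calibration)) {
      0.5 * expected_period * calibration$px_per_h
    } else 10
  }
  s <- stats::sd(y)
  peaks <- find_peaks(y)
  keep <- integer()
  if (length(peaks$index) && s > 0) {
    ok <- peaks$prominence >= prominence_factor * s
    idx <- peaks$index[ok]
    prom <- peaks$prominence[ok]
    for (o in order(prom, decreasing = TRUE)) {
      if (all(abs(idx[o] - idx[keep]) >= min_separation) || !length(keep)) {
        keep <- c(keep, o)
      }
    }
    keep <- sort(idx[keep])
  }
  out <- tibble::tibble(
    position_px = profile$position_px[keep],
    prominence = if (length(keep)) {
      peaks$prominence[match(keep, peaks$index)]
    } else numeric()
  )
  if (!is.null(calibration)) out$time_h <- calibration$pos_to_time(out$position_px)
  structure(out, class = c("ring_set", class(out)),
            provenance = c(provenance(profile),
                           sprintf("detect_rings(min_separation=%g, prominence_factor=%g, polarity=%s)",
                                   min_separation, prominence_factor, polarity)))
}

# Local maxima with topographic prominence. Plateaus take their first
# index. Returns list(index, height, prominence).
find_peaks <- function(y) {
  n <- length(y)
  if (n < 3) return(list(index = integer(), height = numeric(),
                         prominence = numeric()))
  # collapse equal-value runs so quantization plateaus count as one peak
  # (anchored at the plateau's first sample)
  keep_idx <- c(TRUE, diff(y) != 0)
  yc <- y[keep_idx]
  orig <- which(keep_idx)
  if (length(yc) < 3) return(list(index = integer(), height = numeric(),
                                  prominence = numeric()))
  d <- diff(yc)
  cand <- orig[which(utils::head(d, -1) > 0 & utils::tail(d, -1) < 0) + 1]
  prom <- vapply(cand, function(i) {
    h <- y[i]
    left <- if (i > 1) {
      higher <- which(y[1:(i - 1)] > h)
      lo <- if (length(higher)) (max(higher) + 1) else 1
      min(y[lo:i])
    } else h
    right <- if (i < n) {
      higher <- which(y[(i + 1):n] > h)
      hi <- if (length(higher)) (i + min(higher) - 1) else n
      min(y[i:hi])
    } else h
    h - max(left, right)
  }, numeric(1))
  list(index = cand, height = y[cand], prominence = prom)
}

#' Periodogram of a detrended radial profile
#'
#' Magnitude-squared DFT of the mean-removed residual, zero-padded by
#' `pad_factor` and expressed against frequency in cycles per hour via the
#' pixel-to-hour calibration (constant growth makes the pixel grid uniform
#' in time). Rectangular window by default; a Hann window is available.
#' Power is normalized so that the one-sided sum over all bins equals
#' N times the population variance of the input (Parseval).
#'
#' @param profile A detrended `radial_profile` (detrended internally
#'   otherwise, recorded in provenance).
#' @param calibration A [calibrate()] result.
#' @param pad_factor Integer zero-padding factor >= 1. Default 8.
#' @param window `"rectangular"` (default) or `"hann"`.
#' @return A `periodogram` tibble with columns `freq_per_h`, `power` and
#'   attributes `pad_factor`, `n`, `dt_h`, `window`.
#' @export
compute_periodogram <- function(profile, calibration, pad_factor = 8,
                                window = c("rectangular", "hann")) {
  window <- match.arg(window)
  stopifnot(inherits(calibration, "time_calibration"))
  if (pad_factor < 1 || pad_factor != round(pad_factor)) {
    stop("pad_factor must be a positive integer")
  }
  if (!is_detrended(profile)) profile <- detrend_quadratic(profile)
  x <- profile$intensity - mean(profile$intensity)
  n <- length(x)
  if (window == "hann") {
    x <- x * (0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)))
  }
  dt_h <- 1 / calibration$px_per_h
  npad <- pad_factor * n
  X <- stats::fft(c(x, numeric(npad - n)))
  half <- floor(npad / 2)
  k <- 0:half
  mult <- rep(2, length(k))
  mult[1] <- 1
  if (npad %% 2 == 0) mult[length(k)] <- 1
  pw <- mult * Mod(X[k + 1])^2 / npad
  out <- tibble::tibble(freq_per_h = k / (npad * dt_h), power = pw)
  structure(out, class = c("periodogram", class(out)),
            pad_factor = pad_factor, n = n, dt_h = dt_h, window = window,
            provenance = c(provenance(profile),
                           sprintf("compute_periodogram(pad_factor=%d, window=%s)",
                                   pad_factor, window)))
}

#' Estimate the free-running period from a periodogram
#'
#' Locates the power maximum inside the circadian search band, refines it
#' by three-point parabolic interpolation on log power, and converts to a
#' period in hours. The signal-to-noise ratio (peak power over the median
#' in-band power) decides the rhythmicity call.
#'
#' @param pg A [compute_periodogram()] result.
#' @param band Period search band in hours, `c(min, max)`. Default
#'   `c(16, 36)`.
#' @param snr_threshold Rhythmicity threshold on the SNR. Default 10,
#'   calibrated so that pure-noise profiles at the default record length
#'   are called non-rhythmic at least 95% of the time.
#' @return An object of class `period_estimate` with fields `period`
#'   (hours), `peak_power`, `snr`, `rhythmic`, `method_meta`.
#' @export
estimate_period <- function(pg, band = c(16, 36), snr_threshold = 10) {
  stopifnot(inherits(pg, "periodogram"), length(band) == 2, band[1] < band[2])
  f <- pg$freq_per_h
  in_band <- f >= 1 / band[2] & f <= 1 / band[1]
  if (!any(in_band)) stop("search band lies outside the frequency grid")
  pw <- pg$power
  i_band <- which(in_band)
  i_pk <- i_band[which.max(pw[i_band])]
  # 3-point parabolic refinement on log power (falls back to the bin value
  # at grid edges or zero-power neighbours)
  delta <- 0
  if (i_pk > 1 && i_pk < length(f) &&
      all(pw[(i_pk - 1):(i_pk + 1)] > 0)) {
    lp <- log(pw[(i_pk - 1):(i_pk + 1)])
    den <- lp[1] - 2 * lp[2] + lp[3]
    if (den < 0) delta <- 0.5 * (lp[1] - lp[3]) / den
    delta <- max(-0.5, min(0.5, delta))
  }
  df <- f[2] - f[1]
  f_hat <- f[i_pk] + delta * df
  med <- stats::median(pw[i_band])
  snr <- if (med > 0) pw[i_pk] / med else Inf
  structure(
    list(period = 1 / f_hat, peak_power = pw[i_pk], snr = snr,
         rhythmic = is.finite(snr) && snr >= snr_threshold,
         method_meta = list(pad_factor = attr(pg, "pad_factor"),
                            band = band, interpolated = delta != 0,
                            snr_threshold = snr_threshold,
                            window = attr(pg, "window"))),
    class = "period_estimate"
  )
}

#' @export
print.period_estimate <- function(x, ...) {
  cat(sprintf("<period_estimate> %.2f h (SNR %.1f, %s)\n", x$period, x$snr,
              if (x$rhythmic) "rhythmic" else "not rhythmic"))
  invisible(x)
}

#' Ring formation rate in rings per day
#'
#' The number of inter-ring intervals divided by the time spanned between
#' the first and last detected ring, scaled to 24 h. Requires a calibrated
#' ring set (a `time_h` column) or a separate calibration.
#'
#' @param rings A `ring_set` from [detect_rings()].
#' @param calibration A [calibrate()] result (optional if `rings` already
#'   carries `time_h`).
#' @return Rings per 24 h (numeric), or `NA` with a message when fewer
#'   than two rings are available.
#' @export
rings_per_day <- function(rings, calibration = NULL) {
  if (nrow(rings) < 2) {
    message("fewer than two rings: rate undefined")
    return(NA_real_)
  }
  t <- rings[["time_h"]]
  if (is.null(t)) {
    if (is.null(calibration)) stop("calibration required: ring set has no time_h")
    t <- calibration$pos_to_time(rings$position_px)
  }
  (nrow(rings) - 1) / abs(t[length(t)] - t[1]) * 24
}
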