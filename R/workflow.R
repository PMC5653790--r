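#' Assemble a synthetic colony scenario
#'
#' Convenience constructor bundling a schedule, clock and colony model into
#' the ground truth plus a rendered image, the way a photographed plate
#' would arrive: growth under a lighting regime at constant temperature,
#' uneven illumination, camera noise.
#'
#' @param schedule A [light_schedule()].
#' @param clock A [clock_params()].
#' @param colony A [colony_model()].
#' @param illumination An [illumination_field()].
#' @param noise_sd Camera noise SD (grayscale units). Default 2% of the
#'   8-bit range.
#' @param seed Integer RNG seed.
#' @param render `"image"` (default), `"profile"` (1-D only, faster), or
#'   `"none"` (truth only).
#' @return A list with `truth`, and (depending on `render`) `image` and/or
#'   `profile`.
#' @examples
#' sc <- simulate_colony(light_schedule(dd_start = 0), clock_params(24.5),
#'                       colony_model(duration = 96), render = "profile")
#' @export
simulate_colony <- function(schedule = light_schedule(),
                            clock = clock_params(),
                            colony = colony_model(),
                            illumination = illumination_field(),
                            noise_sd = 0.02 * 255, seed = 1L,
                            render = c("image", "profile", "none")) {
  render <- match.arg(render)
  truth <- synthetic_truth(schedule, clock, colony, seed = seed)
  out <- list(truth = truth)
  if (render == "image") {
    ri <- render_colony_image(truth, illumination = illumination,
                              noise_sd = noise_sd, seed = seed)
    out$image <- ri$image
    out$truth <- ri$truth  # seed_center resolved to the image centre
  } else if (render == "profile") {
    out$profile <- render_profile(truth, noise_sd = noise_sd, seed = seed)
  }
  out
}

# Default radial ROI for a synthetic colony image: along +x over the banded
# annulus, from the radius where banding starts to just short of the final
# colony radius (the rectangle an analyst would draw over the rings).
# Profile position 0 then corresponds to radius start_radius.
# Width must stay small relative to the innermost ring radius: rings are
# concentric, so across a wide rectangle they curve away from the short
# side and the transverse average smears band positions inward by about
# width^2/(24*radius) px.
default_roi <- function(truth, width = 16) {
  col <- truth$colony
  roi(anchor = col$seed_center + c(col$start_radius, -(width - 1) / 2),
      length = floor(col$growth_rate * col$duration) - 1,
      width = width, angle = 0)
}

#' Analyze a colony image end to end
#'
#' Runs the full chain on a photograph: ROI extraction, Gaussian smoothing,
#' pseudo flat-field correction, transverse averaging, quadratic
#' detrending, zero-padded DFT periodogram, and in-band period estimation.
#'
#' @param image A [colony_image()].
#' @param roi An [roi()].
#' @param calibration A [calibrate()] result.
#' @param blur_sigma,background_sigma See [profile_from_image()].
#' @param pad_factor,band,snr_threshold See [compute_periodogram()] and
#'   [estimate_period()].
#' @param polarity Ring polarity for ring detection.
#' @return A list with `profile` (detrended), `raw_profile`, `rings`,
#'   `periodogram`, `estimate`, `rings_per_day`.
#' @export
analyze_colony_image <- function(image, roi, calibration, blur_sigma = 3,
                                 background_sigma = roi$length / 4,
                                 pad_factor = 8, band = c(16, 36),
                                 snr_threshold = 10,
                                 polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  raw <- profile_from_image(image, roi, blur_sigma = blur_sigma,
                            background_sigma = background_sigma)
  analyze_profile(raw, calibration, pad_factor = pad_factor, band = band,
                  snr_threshold = snr_threshold, polarity = polarity)
}

#' Analyze a 1-D band profile
#'
#' The profile-level tail of [analyze_colony_image()]: detrend, detect
#' rings, periodogram, period estimate, ring rate.
#'
#' @inheritParams analyze_colony_image
#' @param profile A `radial_profile`.
#' @param expected_period Expected period (h) informing the ring-detection
#'   separation default.
#' @return Same structure as [analyze_colony_image()].
#' @export
analyze_profile <- function(profile, calibration, pad_factor = 8,
                            band = c(16, 36), snr_threshold = 10,
                            polarity = c("dark", "bright"),
                            expected_period = 24) {
  polarity <- match.arg(polarity)
  det <- detrend_quadratic(profile)
  rings <- detect_rings(det, polarity = polarity, calibration = calibration,
                        expected_period = expected_period)
  pg <- compute_periodogram(det, calibration, pad_factor = pad_factor)
  est <- estimate_period(pg, band = band, snr_threshold = snr_threshold)
  list(profile = det, raw_profile = profile, rings = rings,
       periodogram = pg, estimate = est,
       rings_per_day = if (nrow(rings) >= 2) rings_per_day(rings) else NA_real_)
}

#' Period-recovery study on synthetic colonies
#'
#' Simulates seeded replicate colony photographs grown in constant darkness
#' with a known free-running period, pushes each through the full image
#' pipeline, and returns per-seed period estimates. This is the
#' parameter-recovery experiment used to validate the pipeline: the
#' estimates should cluster within half an hour of the true period.
#'
#' @param true_period True free-running period (h).
#' @param n_seeds Number of replicate colonies. Default 50.
#' @param base_seed Integer; replicate seeds are derived from it.
#' @param duration Growth duration (h). Default 144 (six days).
#' @param noise_sd Camera noise SD. Default 2% of the 8-bit range.
#' @param gradient Planar illumination gradient across the frame.
#'   Default 0.1 (+/-5%, i.e. 10% corner to corner).
#' @param growth_rate Radial growth rate (px/h). Default 2.5.
#' @return A tibble with columns `seed`, `true_period`, `estimate_h`,
#'   `snr`, `rhythmic`, `abs_error_h`.
#' @export
frp_recovery_study <- function(true_period, n_seeds = 50, base_seed = 1L,
                               duration = 144, noise_sd = 0.02 * 255,
                               gradient = 0.1, growth_rate = 2.5) {
  seeds <- derive_seeds(base_seed, n_seeds)
  purrr::map_dfr(seeds, function(s) {
    sim <- simulate_colony(
      schedule = light_schedule(dd_start = 0),
      clock = clock_params(free_running_period = true_period),
      colony = colony_model(growth_rate = growth_rate, duration = duration),
      illumination = illumination_field("planar", gradient = gradient),
      noise_sd = noise_sd, seed = s, render = "image")
    res <- analyze_colony_image(sim$image, default_roi(sim$truth),
                                calibrate_from_truth(sim$truth, sim$truth$colony$start_radius))
    tibble::tibble(seed = s, true_period = true_period,
                   estimate_h = res$estimate$period,
                   snr = res$estimate$snr,
                   rhythmic = res$estimate$rhythmic,
                   abs_error_h = abs(res$estimate$period - true_period))
  })
}

#' Jet-lag study on synthetic colonies
#'
#' Simulates replicate colonies entrained to 12:12 LD whose schedule is
#' delayed partway through the run, then estimates the phase shift by
#' segmented cosine fitting on the pipeline profile.
#'
#' @param delay Schedule delay in hours (positive = delay). Default 8.
#' @param n_seeds Number of replicates. Default 20.
#' @param base_seed Integer seed the replicate seeds derive from.
#' @param days_before Days of entrainment before the shift. Default 4.
#' @param days_after Days after the shift. Default 6.
#' @param relaxation_tau Phase re-entrainment time constant (h). Default 36.
#' @param skip_transient Hours skipped after the shift in the post fit.
#'   Default 72.
#' @inheritParams frp_recovery_study
#' @return A tibble with columns `seed`, `delta_h`, `abs_delta_h`,
#'   `uncertainty_h`.
#' @export
jetlag_study <- function(delay = 8, n_seeds = 20, base_seed = 1L,
                         days_before = 4, days_after = 6,
                         relaxation_tau = 36, skip_transient = 72,
                         noise_sd = 0.02 * 255, gradient = 0.1,
                         growth_rate = 2.5) {
  shift_time <- 24 * days_before
  duration <- 24 * (days_before + days_after)
  seeds <- derive_seeds(base_seed, n_seeds)
  purrr::map_dfr(seeds, function(s) {
    sim <- simulate_colony(
      schedule = light_schedule(
        shift_events = data.frame(time = shift_time, delay = delay)),
      clock = clock_params(relaxation_tau = relaxation_tau),
      colony = colony_model(growth_rate = growth_rate, duration = duration),
      illumination = illumination_field("planar", gradient = gradient),
      noise_sd = noise_sd, seed = s, render = "image")
    prof <- profile_from_image(sim$image, default_roi(sim$truth))
    ps <- estimate_phase_shift(prof,
                               calibrate_from_truth(sim$truth,
                                                    sim$truth$colony$start_radius),
                               shift_time = shift_time, period = 24,
                               skip_transient = skip_transient)
    tibble::tibble(seed = s, delta_h = ps$delta, abs_delta_h = abs(ps$delta),
                   uncertainty_h = ps$uncertainty)
  })
}

# deterministic replicate seeds below 2^31 derived from one base seed
derive_seeds <- function(base_seed, n) {
  (as.integer(base_seed) %% 20000L) * 100000L + seq_len(n)
}
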