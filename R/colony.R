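#' Define a growing colony model
#'
#' Geometry and optics of a colony that grows at a constant radial rate and
#' deposits one concentric ring per clock cycle. Ring bands are rendered as
#' a raised cosine of the clock phase, sharpened by an exponent, and are
#' either darker or brighter than the inter-ring zones (`ring_polarity`).
#'
#' @param growth_rate Radial growth rate in pixels per hour. Default 2.5.
#' @param seed_center Pixel coordinates `c(x, y)` of the inoculation point
#'   (0-based, x = column, y = row). Default `c(0, 0)`; set when rendering.
#' @param start_radius Radius (px) at which banding begins (the colony
#'   present at time zero). Default 20.
#' @param duration Growth duration in hours. Default 144 (six days).
#' @param baseline_intensity Mean grayscale level of the colony. Default 180.
#' @param ring_amplitude Peak band contrast in grayscale units. Default 80.
#' @param ring_sharpness Exponent (>= 1) applied to the raised-cosine band;
#'   larger values give narrower rings. Default 2.
#' @param ring_polarity `"dark"` (pigmented rings darker than inter-ring
#'   zones, the default) or `"bright"`.
#'
#' @return An object of class `colony_model`.
#' @export
colony_model <- function(growth_rate = 2.5, seed_center = c(0, 0),
                         start_radius = 20, duration = 144,
                         baseline_intensity = 180, ring_amplitude = 80,
                         ring_sharpness = 2,
                         ring_polarity = c("dark", "bright")) {
  ring_polarity <- match.arg(ring_polarity)
  stopifnot(growth_rate > 0, duration > 0, ring_amplitude >= 0,
            ring_sharpness >= 1, start_radius >= 0)
  structure(
    list(growth_rate = growth_rate, seed_center = seed_center,
         start_radius = start_radius, duration = duration,
         baseline_intensity = baseline_intensity,
         ring_amplitude = ring_amplitude, ring_sharpness = ring_sharpness,
         ring_polarity = ring_polarity),
    class = "colony_model"
  )
}

#' Define an illumination field
#'
#' Smooth multiplicative illumination applied to rendered colony images,
#' emulating the uneven plate illumination that the pseudo flat-field
#' correction later removes. `"planar"` tilts the field linearly across the
#' frame (default +/-10% corner to corner along x); `"vignette"` darkens
#' radially away from a centre.
#'
#' @param kind One of `"uniform"`, `"planar"`, `"vignette"`.
#' @param gradient For `"planar"`: total relative intensity change across
#'   the frame width along x (e.g. 0.2 spans 0.9..1.1). Default 0.2.
#' @param gradient_y For `"planar"`: same along y. Default 0.
#' @param center For `"vignette"`: `c(x, y)` centre (0-based px); defaults
#'   to the image centre at render time.
#' @param width For `"vignette"`: Gaussian width (px) of the falloff.
#' @param depth For `"vignette"`: maximum fractional darkening (< 1).
#'
#' @return An object of class `illumination_field`.
#' @export
illumination_field <- function(kind = c("planar", "uniform", "vignette"),
                               gradient = 0.2, gradient_y = 0,
                               center = NULL, width = 400, depth = 0.2) {
  kind <- match.arg(kind)
  stopifnot(depth < 1)
  structure(
    list(kind = kind, gradient = gradient, gradient_y = gradient_y,
         center = center, width = width, depth = depth),
    class = "illumination_field"
  )
}

# Evaluate the illumination field on a pixel grid; strictly positive.
eval_illumination <- function(field, nx, ny) {
  x <- matrix(rep(0:(nx - 1), each = ny), nrow = ny)
  y <- matrix(rep(0:(ny - 1), times = nx), nrow = ny)
  f <- switch(field$kind,
    uniform = matrix(1, ny, nx),
    planar = 1 + field$gradient * (x / (nx - 1) - 0.5) +
      field$gradient_y * (y / (ny - 1) - 0.5),
    vignette = {
      ctr <- field$center %||% c((nx - 1) / 2, (ny - 1) / 2)
      r2 <- (x - ctr[1])^2 + (y - ctr[2])^2
      1 - field$depth * (1 - exp(-r2 / (2 * field$width^2)))
    }
  )
  if (any(f <= 0)) stop("illumination field must be strictly positive")
  f
}

#' Ground truth for a synthetic colony
#'
#' Combines a schedule, clock and colony model into the ground truth a
#' generated image encodes: ring deposition times, the radii they map to
#' under constant radial growth, the true free-running period and the
#' pixels-per-hour scale. Downstream recovery tests compare estimates
#' against this object.
#'
#' @inheritParams clock_phase_trajectory
#' @param colony A [colony_model()].
#' @param seed Integer RNG seed recorded for provenance.
#' @return An object of class `synthetic_truth` with fields `ring_times`,
#'   `ring_radii`, `true_period_dd`, `px_per_h`, `schedule`, `clock`,
#'   `colony`, `seed`.
#' @examples
#' synthetic_truth(light_schedule(dd_start = 0), clock_params(24.5),
#'                 colony_model(), seed = 1)
#' @export
synthetic_truth <- function(schedule, clock, colony, seed = 1L) {
  stopifnot(inherits(colony, "colony_model"))
  times <- ring_deposition_times(schedule, clock, colony$duration)
  structure(
    list(ring_times = times,
         ring_radii = colony$start_radius + colony$growth_rate * times,
         true_period_dd = clock$free_running_period,
         px_per_h = colony$growth_rate,
         schedule = schedule, clock = clock, colony = colony,
         seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d rings over %g h, FRP %g h, %g px/h\n",
              length(x$ring_times), x$colony$duration, x$true_period_dd,
              x$px_per_h))
  invisible(x)
}

# Band value in [0,1] at radii `r` (vector): raised cosine of the realized
# clock phase at the deposition time mapped to each radius, sharpened.
# Zero outside the banded annulus [start_radius, start_radius + v*duration].
band_at_radius <- function(truth, r) {
  col <- truth$colony
  t <- (r - col$start_radius) / col$growth_rate
  inside <- t >= 0 & t <= col$duration
  b <- numeric(length(r))
  if (any(inside)) {
    phi <- phase_cycles_at(truth$schedule, truth$clock, t[inside])
    p0 <- deposition_level(truth$schedule, truth$clock)
    b[inside] <- ((1 + cos(2 * pi * (phi - p0))) / 2)^col$ring_sharpness
  }
  b
}

#' Render a 1-D radial band profile
#'
#' Renders intensity as a function of radial position: a low-order trend,
#' plus ring bands (raised cosine of clock phase, sharpened, signed by ring
#' polarity), plus i.i.d. Gaussian camera noise. This is the 1-D analogue of
#' a photographed colony after collapsing to a radial profile.
#'
#' @param truth A [synthetic_truth()].
#' @param trend_coeffs Quadratic trend coefficients `c(a0, a1, a2)` so that
#'   trend(x) = a0 + a1 x + a2 x^2 in grayscale units; defaults to the flat
#'   colony baseline.
#' @param noise_sd Gaussian noise standard deviation (grayscale units).
#'   Default 2% of the 8-bit dynamic range.
#' @param seed Integer RNG seed; identical seeds give identical profiles.
#' @return A `radial_profile` tibble with columns `position_px`,
#'   `intensity`.
#' @export
render_profile <- function(truth, trend_coeffs = NULL, noise_sd = 0.02 * 255,
                           seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  col <- truth$colony
  if (is.null(trend_coeffs)) trend_coeffs <- c(col$baseline_intensity, 0, 0)
  n <- floor(col$start_radius + col$growth_rate * col$duration) + 1
  x <- 0:(n - 1)
  sgn <- if (col$ring_polarity == "dark") -1 else 1
  intensity <- trend_coeffs[1] + trend_coeffs[2] * x + trend_coeffs[3] * x^2 +
    sgn * col$ring_amplitude * band_at_radius(truth, x)
  if (noise_sd > 0) {
    intensity <- intensity + withr::with_seed(seed, stats::rnorm(n, 0, noise_sd))
  }
  new_radial_profile(x, intensity,
                     provenance = sprintf("render_profile(seed=%d)", seed))
}

#' Render a synthetic colony photograph
#'
#' Renders a radially symmetric banded colony around `seed_center`
#' following the same radial law as [render_profile()], multiplies by an
#' illumination field, adds Gaussian camera noise and quantizes to the
#' requested bit depth.
#'
#' @inheritParams render_profile
#' @param illumination An [illumination_field()]. Default planar +/-10%.
#' @param image_size `c(nx, ny)` in pixels, or a single number for a square
#'   image; must contain the final colony radius around `seed_center`.
#' @param bit_depth 8, 16 or `"float"` (no quantization).
#' @return A list with elements `image` (a `colony_image`) and `truth`
#'   (the input truth, unchanged).
#' @export
render_colony_image <- function(truth, illumination = illumination_field(),
                                noise_sd = 0.02 * 255, image_size = NULL,
                                bit_depth = 8, seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(illumination, "illumination_field"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  col <- truth$colony
  r_final <- col$start_radius + col$growth_rate * col$duration
  if (is.null(image_size)) image_size <- 2 * ceiling(r_final) + 21
  if (length(image_size) == 1) image_size <- c(image_size, image_size)
  nx <- image_size[1]; ny <- image_size[2]
  if (all(col$seed_center == c(0, 0))) {
    col$seed_center <- c((nx - 1) / 2, (ny - 1) / 2)
    truth$colony <- col
  }
  cx <- col$seed_center[1]; cy <- col$seed_center[2]
  if (cx < 0 || cx > nx - 1 || cy < 0 || cy > ny - 1) {
    stop("seed_center must lie inside the image")
  }
  if (cx - r_final < 0 || cx + r_final > nx - 1 ||
      cy - r_final < 0 || cy + r_final > ny - 1) {
    stop("final colony radius ", round(r_final), " px does not fit inside ",
         nx, "x", ny, " image")
  }
  x <- matrix(rep(0:(nx - 1), each = ny), nrow = ny)
  y <- matrix(rep(0:(ny - 1), times = nx), nrow = ny)
  r <- sqrt((x - cx)^2 + (y - cy)^2)
  sgn <- if (col$ring_polarity == "dark") -1 else 1
  base <- col$baseline_intensity +
    sgn * col$ring_amplitude * band_at_radius(truth, as.vector(r))
  pix <- matrix(base, ny, nx) * eval_illumination(illumination, nx, ny)
  if (noise_sd > 0) {
    pix <- pix + withr::with_seed(seed, matrix(stats::rnorm(nx * ny, 0, noise_sd), ny, nx))
  }
  img <- colony_image(quantize(pix, bit_depth), bit_depth = bit_depth,
                      metadata = list(seed = seed,
                                      capture_time = col$duration))
  list(image = img, truth = truth)
}

quantize <- function(pix, bit_depth) {
  if (identical(bit_depth, "float")) return(pix)
  top <- 2^bit_depth - 1
  pmin(pmax(round(pix), 0), top)
}
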