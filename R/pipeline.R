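#' Define a rectangular radial region of interest
#'
#' The ROI is a rotated rectangle that extends radially from the seed
#' (inoculation point) towards the colony border, so that ring bands run
#' approximately parallel to its short side. `anchor` is the seed-end
#' corner of the rectangle's long axis midline; `angle` orients the radial
#' axis (degrees, 0 = increasing x, 90 = increasing y).
#'
#' @param anchor `c(x, y)` pixel coordinates (0-based) of the seed end.
#' @param length Radial extent in pixels (>= 32).
#' @param width Transverse extent in pixels (>= 4).
#' @param angle Orientation of the radial axis in degrees. Default 0.
#' @return An object of class `roi`.
#' @export
roi <- function(anchor, length, width, angle = 0) {
  stopifnot(length >= 32, width >= 4, base::length(anchor) == 2)
  structure(list(anchor = as.numeric(anchor), length = length,
                 width = width, angle = angle), class = "roi")
}

#' Extract a radial patch from a colony image
#'
#' Samples the rotated ROI rectangle with bilinear interpolation. The
#' first dimension of the returned patch is the radial axis, increasing
#' away from the seed; the second is the transverse axis.
#'
#' @param image A [colony_image()].
#' @param roi An [roi()].
#' @return A numeric matrix (`length` x `width`) with a provenance
#'   attribute.
#' @export
extract_roi <- function(image, roi) {
  stopifnot(inherits(image, "colony_image"), inherits(roi, "roi"))
  a <- roi$angle * pi / 180
  u <- c(cos(a), sin(a))            # radial unit vector
  w <- c(-sin(a), cos(a))           # transverse unit vector
  i <- 0:(roi$length - 1)
  j <- 0:(roi$width - 1)
  xs <- roi$anchor[1] + outer(i * u[1], j * w[1], "+")
  ys <- roi$anchor[2] + outer(i * u[2], j * w[2], "+")
  nx <- ncol(image$pixels); ny <- nrow(image$pixels)
  if (min(xs) < 0 || max(xs) > nx - 1 || min(ys) < 0 || max(ys) > ny - 1) {
    stop("ROI extends outside the image after rotation")
  }
  patch <- matrix(bilinear_sample(image$pixels, as.vector(xs), as.vector(ys)),
                  nrow = roi$length)
  attr(patch, "provenance") <- sprintf(
    "extract_roi(anchor=(%g,%g), length=%d, width=%d, angle=%g)",
    roi$anchor[1], roi$anchor[2], roi$length, roi$width, roi$angle)
  patch
}

# bilinear interpolation at 0-based (x, y); pixels[row=y+1, col=x+1]
bilinear_sample <- function(pixels, x, y) {
  x0 <- floor(x); y0 <- floor(y)
  nx <- ncol(pixels); ny <- nrow(pixels)
  x1 <- pmin(x0 + 1, nx - 1); y1 <- pmin(y0 + 1, ny - 1)
  fx <- x - x0; fy <- y - y0
  idx <- function(yy, xx) pixels[cbind(yy + 1, xx + 1)]
  (1 - fx) * (1 - fy) * idx(y0, x0) + fx * (1 - fy) * idx(y0, x1) +
    (1 - fx) * fy * idx(y1, x0) + fx * fy * idx(y1, x1)
}

# 1-D convolution with a symmetric kernel, reflective boundaries
conv1d_reflect <- function(v, kern) {
  r <- (length(kern) - 1) / 2
  n <- length(v)
  # symmetric reflection including the edge sample: d c b a | a b c d
  left <- v[pmin(pmax(r:1, 1), n)]
  right <- v[pmin(pmax(n:(n - r + 1), 1), n)]
  vp <- c(left, v, right)
  out <- stats::filter(vp, kern, sides = 2)
  as.numeric(out[(r + 1):(r + n)])
}

gaussian_kernel <- function(sigma) {
  r <- max(1, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k / sum(k)
}

#' Gaussian smoothing of a patch or profile
#'
#' Separable Gaussian convolution with reflective boundary handling;
#' `sigma = 0` is the identity. Used to remove high-frequency camera noise
#' before further processing (default sigma 3 px).
#'
#' @param patch A numeric matrix (radial x transverse) or numeric vector.
#' @param sigma Gaussian standard deviation in pixels. Default 3.
#' @return Smoothed object of the same shape, with provenance appended.
#' @export
gaussian_blur <- function(patch, sigma = 3) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(log_step(patch, "gaussian_blur(sigma=0)"))
  k <- gaussian_kernel(sigma)
  if (is.matrix(patch)) {
    out <- apply(patch, 2, conv1d_reflect, kern = k)
    out <- t(apply(out, 1, conv1d_reflect, kern = k))
    if (ncol(patch) == 1) out <- matrix(as.vector(out), ncol = 1)
  } else {
    out <- conv1d_reflect(patch, k)
  }
  attributes(out) <- utils::modifyList(attributes(patch) %||% list(),
                                       list(dim = dim(out)))
  log_step(out, sprintf("gaussian_blur(sigma=%g)", sigma))
}

#' Pseudo flat-field illumination correction
#'
#' Removes smooth illumination gradients by dividing the patch by a heavily
#' blurred copy of itself and rescaling by the mean of the blurred copy, so
#' the output keeps the input's intensity scale. The background blur scale
#' must be much larger than the ring spacing, or the correction starts to
#' erase the rings themselves.
#'
#' @param patch Numeric matrix or vector.
#' @param background_sigma Gaussian sigma (px) of the background estimate.
#' @param expected_spacing Optional expected ring spacing (px); a warning
#'   is issued if `background_sigma` is less than five times this.
#' @return Corrected patch with provenance appended.
#' @export
pseudo_flat_field <- function(patch, background_sigma,
                              expected_spacing = NULL) {
  stopifnot(background_sigma > 0)
  if (!is.null(expected_spacing) && background_sigma < 5 * expected_spacing) {
    warning("background_sigma is less than 5x the expected ring spacing; ",
            "the flat-field correction may attenuate the rings")
  }
  if (all(patch == 0)) stop("degenerate all-zero patch")
  offset <- 0
  if (min(patch) <= 0) {
    offset <- -min(patch) + 1e-6 * diff(range(patch))
    patch <- patch + offset
  }
  bg <- gaussian_blur(patch, background_sigma)
  out <- patch / bg * mean(bg)
  attributes(out) <- utils::modifyList(attributes(patch) %||% list(),
                                       list(dim = dim(out)))
  entry <- sprintf("pseudo_flat_field(background_sigma=%g%s)",
                   background_sigma,
                   if (offset > 0) sprintf(", offset=%g", offset) else "")
  log_step(out, entry)
}

#' Collapse a radial patch to a 1-D profile
#'
#' Averages intensity over the transverse axis (all pixels sharing a radial
#' coordinate), yielding intensity as a function of radial position.
#'
#' @param patch Numeric matrix, radial axis first, at least 4 px wide
#'   (1 px is accepted for degenerate single-column patches).
#' @return A `radial_profile` tibble.
#' @export
collapse_profile <- function(patch) {
  stopifnot(is.matrix(patch))
  prof <- new_radial_profile(0:(nrow(patch) - 1), rowMeans(patch),
                             provenance = provenance(patch))
  log_step(prof, sprintf("collapse_profile(width=%d)", ncol(patch)))
}

#' Full preprocessing chain: image to radial profile
#'
#' Applies, in order: ROI extraction, Gaussian smoothing (default sigma 3),
#' pseudo flat-field illumination correction, and transverse averaging,
#' reproducing the standard preprocessing of colony ring photographs.
#'
#' @param image A [colony_image()].
#' @param roi An [roi()].
#' @param blur_sigma Smoothing sigma (px). Default 3.
#' @param background_sigma Flat-field background sigma (px); default a
#'   quarter of the ROI length.
#' @param flat_field Apply the flat-field stage? Default `TRUE`.
#' @return A `radial_profile` with the complete provenance log.
#' @export
profile_from_image <- function(image, roi, blur_sigma = 3,
                               background_sigma = roi$length / 4,
                               flat_field = TRUE) {
  patch <- extract_roi(image, roi)
  patch <- gaussian_blur(patch, blur_sigma)
  if (flat_field) patch <- pseudo_flat_field(patch, background_sigma)
  collapse_profile(patch)
}
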