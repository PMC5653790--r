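#' Construct a colony image object
#'
#' A thin wrapper around a numeric pixel matrix (rows = y, columns = x,
#' grayscale units on the bit-depth scale) with its bit depth and free-form
#' metadata (temperature, schedule summary, capture time, ...).
#'
#' @param pixels Numeric matrix of intensities.
#' @param bit_depth 8, 16 or `"float"`.
#' @param metadata Named list of metadata.
#' @return An object of class `colony_image`.
#' @export
colony_image <- function(pixels, bit_depth = 8, metadata = list()) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (nrow(pixels) < 64 || ncol(pixels) < 64) {
    stop("colony images must be at least 64x64 pixels")
  }
  if (!identical(bit_depth, "float")) {
    top <- 2^bit_depth - 1
    if (min(pixels) < 0 || max(pixels) > top) {
      stop("pixel intensities outside the ", bit_depth, "-bit range")
    }
  }
  structure(list(pixels = pixels, bit_depth = bit_depth, metadata = metadata),
            class = "colony_image")
}

#' @export
print.colony_image <- function(x, ...) {
  cat(sprintf("<colony_image> %dx%d px, %s-bit\n", ncol(x$pixels),
              nrow(x$pixels), as.character(x$bit_depth)))
  invisible(x)
}

#' @export
dim.colony_image <- function(x) dim(x$pixels)

#' Read a colony photograph
#'
#' Reads a grayscale (or RGB, converted to Rec. 601 luminance) PNG or TIFF
#' into a [colony_image()]. Intensities are returned on the original
#' bit-depth scale (0..255 for 8-bit, 0..65535 for 16-bit). If a sidecar
#' YAML file `<path>.yaml` exists its contents are attached as metadata.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A `colony_image`.
#' @export
read_colony_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    bit_depth <- 8L
    if (!is.null(attr(arr, "bit.depth"))) bit_depth <- attr(arr, "bit.depth")
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = FALSE)
    if (is.list(arr)) {
      if (length(arr) > 1) stop("multi-page TIFF not supported: ", path)
      arr <- arr[[1]]
    }
    bit_depth <- attr(arr, "bits.per.sample") %||% 8L
  } else {
    stop("unsupported image format: .", ext, " (use PNG or TIFF)")
  }
  if (length(dim(arr)) == 3) {
    # Rec. 601 luminance; alpha channel (if any) ignored
    arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
  }
  scale <- if (identical(bit_depth, "float")) 1 else 2^bit_depth - 1
  meta <- list()
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) meta <- yaml::read_yaml(sidecar)
  colony_image(arr * scale, bit_depth = bit_depth, metadata = meta)
}

#' Write a colony image to disk
#'
#' Writes PNG (8-bit) or TIFF (8- or 16-bit). Metadata, if any, is written
#' to a sidecar YAML file `<path>.yaml`.
#'
#' @param image A [colony_image()].
#' @param path Output path; the extension selects the format.
#' @param write_sidecar Write metadata to `<path>.yaml`? Default `TRUE`
#'   when metadata is present.
#' @return `path`, invisibly.
#' @export
write_colony_image <- function(image, path,
                               write_sidecar = length(image$metadata) > 0) {
  stopifnot(inherits(image, "colony_image"))
  ext <- tolower(tools::file_ext(path))
  bd <- if (identical(image$bit_depth, "float")) 16 else image$bit_depth
  norm <- image$pixels / (2^bd - 1)
  norm <- pmin(pmax(norm, 0), 1)
  if (ext == "png") {
    png::writePNG(norm, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = bd)
  } else {
    stop("unsupported image format: .", ext, " (use PNG or TIFF)")
  }
  if (isTRUE(write_sidecar)) {
    yaml::write_yaml(image$metadata, paste0(path, ".yaml"))
  }
  invisible(path)
}
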