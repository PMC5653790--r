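#' @keywords internal
#' @noRd
new_radial_profile <- function(position_px, intensity, time_h = NULL,
                               provenance = character()) {
  stopifnot(length(position_px) == length(intensity),
            length(position_px) >= 2,
            all(diff(position_px) > 0))
  df <- tibble::tibble(position_px = as.numeric(position_px),
                       intensity = as.numeric(intensity))
  if (!is.null(time_h)) df$time_h <- as.numeric(time_h)
  structure(df, class = c("radial_profile", class(df)),
            provenance = provenance)
}

#' Coerce a data frame to a radial profile
#'
#' @param x A data frame with columns `position_px` and `intensity`
#'   (optionally `time_h`), e.g. read from a two-column CSV.
#' @return A `radial_profile` tibble.
#' @export
as_radial_profile <- function(x) {
  stopifnot(all(c("position_px", "intensity") %in% names(x)))
  new_radial_profile(x$position_px, x$intensity, x[["time_h"]],
                     provenance = attr(x, "provenance") %||% character())
}

# append a provenance entry, preserving class/attrs
log_step <- function(profile, entry) {
  attr(profile, "provenance") <- c(attr(profile, "provenance"), entry)
  profile
}

#' Provenance log of a profile or patch
#'
#' Every pipeline stage appends a log entry describing what it did; this
#' accessor returns the log.
#'
#' @param x A `radial_profile` or patch matrix produced by the pipeline.
#' @return Character vector of processing steps.
#' @export
provenance <- function(x) attr(x, "provenance") %||% character()

#' Write / read a radial profile as CSV
#'
#' Two columns, `position_px` and `intensity` (plus `time_h` when
#' calibrated). The provenance log is written alongside as
#' `<path>.provenance.json`.
#'
#' @param profile A `radial_profile`.
#' @param path Output CSV path.
#' @return `path` invisibly (write); a `radial_profile` (read).
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  prov <- provenance(profile)
  if (length(prov)) {
    jsonlite::write_json(prov, paste0(path, ".provenance.json"))
  }
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  as_radial_profile(df)
}
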