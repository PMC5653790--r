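#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a period estimate
#'
#' @param x A `period_estimate` from [estimate_period()].
#' @param ... Unused.
#' @return One-row tibble: `period_h`, `peak_power`, `snr`, `rhythmic`.
#' @export
tidy.period_estimate <- function(x, ...) {
  tibble::tibble(period_h = x$period, peak_power = x$peak_power,
                 snr = x$snr, rhythmic = x$rhythmic)
}

#' @rdname tidy.period_estimate
#' @export
glance.period_estimate <- function(x, ...) {
  tibble::tibble(period_h = x$period, snr = x$snr, rhythmic = x$rhythmic,
                 pad_factor = x$method_meta$pad_factor,
                 band_min_h = x$method_meta$band[1],
                 band_max_h = x$method_meta$band[2],
                 snr_threshold = x$method_meta$snr_threshold,
                 window = x$method_meta$window)
}

#' Tidy a phase-shift estimate
#'
#' @param x A `phase_shift_estimate` from [estimate_phase_shift()].
#' @param ... Unused.
#' @return One-row tibble: `delta_h`, `pre_phase_h`, `post_phase_h`,
#'   `period_h`, `skipped_transient_h`, `uncertainty_h`.
#' @export
tidy.phase_shift_estimate <- function(x, ...) {
  tibble::tibble(delta_h = x$delta, pre_phase_h = x$pre_phase,
                 post_phase_h = x$post_phase, period_h = x$period_used,
                 skipped_transient_h = x$skipped_transient,
                 uncertainty_h = x$uncertainty)
}

#' Tidy a temperature-compensation result
#'
#' `tidy()` returns the per-temperature summary; `glance()` the one-row
#' overall result (Q10, ANOVA F and p).
#'
#' @param x A `compensation_result` from [compensation_report()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.compensation_result <- function(x, ...) x$groups

#' @rdname tidy.compensation_result
#' @export
glance.compensation_result <- function(x, ...) {
  tibble::tibble(q10 = x$q10, q10_display = x$q10_display,
                 ref_low_C = x$reference_pair[1],
                 ref_high_C = x$reference_pair[2],
                 anova_F = x$anova$statistic, anova_p = x$anova$p_value,
                 anova_degenerate = x$anova$degenerate)
}

#' Tidy an actogram into long format
#'
#' @param x An `actogram` from [build_actogram()].
#' @param ... Unused.
#' @return A tibble with columns `row`, `hour` (within-row bin centre) and
#'   `intensity`.
#' @export
tidy.actogram <- function(x, ...) {
  centers <- (seq_len(ncol(x$rows)) - 0.5) * x$bin_width
  tidyr::expand_grid(row = seq_len(nrow(x$rows)), hour = centers) |>
    dplyr::mutate(intensity = as.vector(t(x$rows)))
}

#' Tidy a synthetic ground truth
#'
#' @param x A `synthetic_truth`.
#' @param ... Unused.
#' @return A tibble with one row per ring: `ring`, `time_h`, `radius_px`.
#' @export
tidy.synthetic_truth <- function(x, ...) {
  tibble::tibble(ring = seq_along(x$ring_times), time_h = x$ring_times,
                 radius_px = x$ring_radii)
}

#' Write a synthetic ground truth as JSON
#'
#' @param truth A `synthetic_truth`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(ring_times = truth$ring_times, ring_radii = truth$ring_radii,
         true_period_dd = truth$true_period_dd, px_per_h = truth$px_per_h,
         seed = truth$seed,
         schedule = list(
           cycle_length = truth$schedule$cycle_length,
           light_fraction = truth$schedule$light_fraction,
           phase_offset = truth$schedule$phase_offset,
           dd_start = truth$schedule$dd_start,
           shift_events = truth$schedule$shift_events)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
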