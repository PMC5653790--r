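#' Temperature coefficient Q10 of a circadian rhythm
#'
#' Q10 measures how much the oscillation rate (1/period) changes per 10
#' degree C. A perfectly temperature-compensated clock has Q10 = 1; most
#' uncompensated biochemical rates have Q10 of 2-3. Defined on rates,
#'
#' \deqn{Q_{10} = (r_{high}/r_{low})^{10/(T_{high}-T_{low})}
#'             = (P_{low}/P_{high})^{10/(T_{high}-T_{low})}}
#'
#' where `r = 1/P` is the oscillation rate.
#'
#' @param period_low Period (h) at the lower temperature.
#' @param t_low Lower temperature (degrees C).
#' @param period_high Period (h) at the higher temperature.
#' @param t_high Higher temperature (degrees C); must exceed `t_low`.
#' @return Dimensionless Q10.
#' @examples
#' q10(26.8, 10, 24.5, 20)  # ~1.09, i.e. 1.1 at one decimal
#' @export
q10 <- function(period_low, t_low, period_high, t_high) {
  if (t_high <= t_low) stop("t_high must exceed t_low")
  if (period_low <= 0 || period_high <= 0) stop("periods must be positive")
  (period_low / period_high)^(10 / (t_high - t_low))
}

#' One-way ANOVA across temperature groups
#'
#' Classical fixed-effects one-way ANOVA of period estimates across
#' temperature groups (equal-variance F test).
#'
#' @param periods A data frame with columns `temperature_C` and `period_h`,
#'   or a named list of numeric period vectors.
#' @return A tibble with columns `statistic` (F), `p_value`, `df_between`,
#'   `df_within`, and `degenerate` (`TRUE` when within-group variance is
#'   zero and F is undefined).
#' @export
anova_periods <- function(periods) {
  df <- as_period_table(periods)
  groups <- split(df$period_h, df$temperature_C)
  if (length(groups) < 2) stop("need at least two temperature groups")
  if (any(vapply(groups, length, 1L) < 2)) stop("every group needs n >= 2")
  within_var <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  if (within_var == 0) {
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                          df_between = length(groups) - 1,
                          df_within = nrow(df) - length(groups),
                          degenerate = TRUE))
  }
  ow <- stats::oneway.test(period_h ~ factor(temperature_C), data = df,
                           var.equal = TRUE)
  tibble::tibble(statistic = unname(ow$statistic),
                 p_value = unname(ow$p.value),
                 df_between = unname(ow$parameter[1]),
                 df_within = unname(ow$parameter[2]),
                 degenerate = FALSE)
}

as_period_table <- function(periods) {
  if (is.data.frame(periods)) {
    stopifnot(all(c("temperature_C", "period_h") %in% names(periods)))
    tibble::as_tibble(periods)
  } else {
    stopifnot(is.list(periods), !is.null(names(periods)))
    purrr::map_dfr(names(periods), function(nm) {
      tibble::tibble(temperature_C = as.numeric(nm), period_h = periods[[nm]])
    })
  }
}

#' Temperature-compensation report
#'
#' Aggregates per-plate free-running period estimates by temperature,
#' computes group means, SDs and SEMs, the Q10 between a reference pair of
#' temperatures (on the group means), and a one-way ANOVA across all
#' groups.
#'
#' @param periods Data frame with columns `temperature_C`, `period_h` and
#'   optionally `plate_id`, or a named list of period vectors.
#' @param reference_pair The two temperatures (degrees C) used for Q10.
#'   Default `c(10, 20)`.
#' @return An object of class `compensation_result` with fields `groups`
#'   (summary tibble: temperature_C, n, mean_h, sd_h, sem_h), `q10`,
#'   `q10_display` (one decimal), `anova` (tibble from [anova_periods()])
#'   and `reference_pair`.
#' @examples
#' compensation_report(list(`10` = c(26.1, 26.8, 27.5),
#'                          `14` = c(24.0, 24.4, 24.8),
#'                          `20` = c(24.1, 24.5, 24.9)))
#' @export
compensation_report <- function(periods, reference_pair = c(10, 20)) {
  df <- as_period_table(periods)
  stopifnot(length(reference_pair) == 2)
  groups <- df |>
    dplyr::group_by(temperature_C) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_h = mean(period_h),
                     sd_h = stats::sd(period_h),
                     sem_h = stats::sd(period_h) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::arrange(temperature_C)
  ref <- sort(reference_pair)
  if (!all(ref %in% groups$temperature_C)) {
    stop("reference temperatures not all present in the data")
  }
  p_lo <- groups$mean_h[groups$temperature_C == ref[1]]
  p_hi <- groups$mean_h[groups$temperature_C == ref[2]]
  q <- q10(p_lo, ref[1], p_hi, ref[2])
  an <- if (dplyr::n_distinct(df$temperature_C) >= 2 &&
            all(groups$n >= 2)) {
    anova_periods(df)
  } else {
    tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                   df_between = NA_real_, df_within = NA_real_,
                   degenerate = TRUE)
  }
  structure(
    list(groups = groups, q10 = q, q10_display = round(q, 1), anova = an,
         reference_pair = ref),
    class = "compensation_result"
  )
}

#' @export
print.compensation_result <- function(x, ...) {
  cat("<compensation_result>\n")
  print(x$groups)
  cat(sprintf("Q10(%g-%g C) = %.3f (%.1f at one decimal)\n",
              x$reference_pair[1], x$reference_pair[2], x$q10, x$q10_display))
  if (!isTRUE(x$anova$degenerate)) {
    cat(sprintf("one-way ANOVA: F(%g, %g) = %.3f, p = %.3f\n",
                x$anova$df_between, x$anova$df_within,
                x$anova$statistic, x$anova$p_value))
  } else {
    cat("one-way ANOVA: degenerate (no within-group variance)\n")
  }
  invisible(x)
}

#' Write a compensation report as JSON + CSV summary
#'
#' @param result A [compensation_report()] result.
#' @param json_path Output JSON path (full report).
#' @param csv_path Optional output CSV path (group summary table).
#' @return `json_path`, invisibly.
#' @export
write_compensation_report <- function(result, json_path, csv_path = NULL) {
  stopifnot(inherits(result, "compensation_result"))
  jsonlite::write_json(
    list(groups = result$groups, q10 = result$q10,
         q10_display = result$q10_display,
         reference_pair = result$reference_pair, anova = result$anova),
    json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(result$groups), csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
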