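#' Config-driven pipeline runs
#'
#' `run_simulate()`, `run_analyze()`, `run_actogram()` and
#' `run_compensation()` expose the pipeline as reproducible, YAML-configured
#' commands: each reads a config (path or list), materializes all defaults,
#' writes its outputs plus the resolved config into `out_dir`, and is
#' deterministic given (config, seed). A thin command-line wrapper around
#' these functions ships in `inst/scripts/ringclock`.
#'
#' Config errors signal condition class `ringclock_config_error`; unreadable
#' or inconsistent data signal `ringclock_data_error`.
#'
#' @param config Path to a YAML config or an equivalent named list. See the
#'   bundled examples under `system.file("extdata/scenarios", package =
#'   "ringclock")`.
#' @param out_dir Output directory (created if missing).
#' @param seed Optional integer overriding the config seed.
#' @return A list of the objects produced, invisibly; files are written to
#'   `out_dir`.
#' @name run_commands
NULL

config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("ringclock_config_error",
                                             "error", "condition")))
}
data_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("ringclock_data_error",
                                             "error", "condition")))
}

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) config_error("config file not found: ", config)
    config <- tryCatch(yaml::read_yaml(config),
                       error = function(e) config_error("invalid YAML: ",
                                                        conditionMessage(e)))
  }
  if (!is.list(config)) config_error("config must be a YAML file or a list")
  config
}

pluck_num <- function(block, name, default) {
  v <- block[[name]] %||% default
  if (!is.numeric(v)) config_error("field '", name, "' must be numeric")
  v
}

schedule_from_config <- function(cfg) {
  cfg <- cfg %||% list()
  ev <- cfg$shift_events
  if (!is.null(ev)) {
    ev <- purrr::map_dfr(ev, ~ tibble::tibble(time = .x$time, delay = .x$delay))
  }
  tryCatch(
    light_schedule(cycle_length = pluck_num(cfg, "cycle_length", 24),
                   light_fraction = pluck_num(cfg, "light_fraction", 0.5),
                   phase_offset = pluck_num(cfg, "phase_offset", 0),
                   dd_start = cfg$dd_start, shift_events = ev),
    error = function(e) config_error("bad schedule block: ",
                                     conditionMessage(e)))
}

clock_from_config <- function(cfg) {
  cfg <- cfg %||% list()
  clock_params(free_running_period = pluck_num(cfg, "free_running_period", 24.5),
               entrained_phase = pluck_num(cfg, "entrained_phase", 0),
               relaxation_tau = pluck_num(cfg, "relaxation_tau", 36))
}

colony_from_config <- function(cfg) {
  cfg <- cfg %||% list()
  colony_model(growth_rate = pluck_num(cfg, "growth_rate", 2.5),
               start_radius = pluck_num(cfg, "start_radius", 20),
               duration = pluck_num(cfg, "duration", 144),
               baseline_intensity = pluck_num(cfg, "baseline_intensity", 180),
               ring_amplitude = pluck_num(cfg, "ring_amplitude", 80),
               ring_sharpness = pluck_num(cfg, "ring_sharpness", 2),
               ring_polarity = cfg$ring_polarity %||% "dark")
}

illumination_from_config <- function(cfg) {
  cfg <- cfg %||% list()
  illumination_field(kind = cfg$kind %||% "planar",
                     gradient = pluck_num(cfg, "gradient", 0.2),
                     gradient_y = pluck_num(cfg, "gradient_y", 0),
                     center = if (!is.null(cfg$center)) unlist(cfg$center),
                     width = pluck_num(cfg, "width", 400),
                     depth = pluck_num(cfg, "depth", 0.2))
}

calibration_from_config <- function(cfg, truth = NULL) {
  if (!is.null(cfg$anchor_a) && !is.null(cfg$anchor_b)) {
    return(calibrate(unlist(cfg$anchor_a), unlist(cfg$anchor_b)))
  }
  if (!is.null(cfg$truth_json)) {
    if (!file.exists(cfg$truth_json)) {
      data_error("truth JSON not found: ", cfg$truth_json)
    }
    tj <- jsonlite::read_json(cfg$truth_json, simplifyVector = TRUE)
    n <- length(tj$ring_times)
    if (n < 2) data_error("truth JSON has fewer than two rings")
    return(calibrate(c(tj$ring_radii[1], tj$ring_times[1]),
                     c(tj$ring_radii[n], tj$ring_times[n])))
  }
  if (!is.null(truth)) return(calibrate_from_truth(truth))
  config_error("calibration block needs anchor_a/anchor_b or truth_json")
}

echo_config <- function(config, out_dir) {
  yaml::write_yaml(config, file.path(out_dir, "resolved_config.yaml"))
}

#' @rdname run_commands
#' @export
run_simulate <- function(config, out_dir, seed = NULL) {
  config <- read_run_config(config)
  sc <- config$scenario %||% config_error("config needs a 'scenario' block")
  seed <- as.integer(seed %||% sc$seed %||% 1L)
  sc$seed <- seed
  config$scenario <- sc
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_colony(schedule = schedule_from_config(sc$schedule),
                         clock = clock_from_config(sc$clock),
                         colony = colony_from_config(sc$colony),
                         illumination = illumination_from_config(sc$illumination),
                         noise_sd = pluck_num(sc, "noise_sd", 0.02 * 255),
                         seed = seed, render = "image")
  img_path <- file.path(out_dir, sc$image_file %||% "colony.png")
  write_colony_image(sim$image, img_path, write_sidecar = FALSE)
  write_truth_json(sim$truth, file.path(out_dir, "truth.json"))
  prof <- profile_from_image(sim$image, default_roi(sim$truth))
  # express positions as radii from the seed so they line up with the truth
  # JSON ring_radii (the ROI starts at the banded annulus, not the seed)
  prof$position_px <- prof$position_px + sim$truth$colony$start_radius
  write_profile_csv(prof, file.path(out_dir, "profile.csv"))
  echo_config(config, out_dir)
  invisible(list(image = sim$image, truth = sim$truth, profile = prof,
                 image_path = img_path))
}

resolve_profile_input <- function(config, out_dir) {
  inp <- config$input %||% config_error("config needs an 'input' block")
  log <- character()
  if (!is.null(inp$profile_csv)) {
    if (!file.exists(inp$profile_csv)) {
      data_error("profile CSV not found: ", inp$profile_csv)
    }
    prof <- tryCatch(read_profile_csv(inp$profile_csv),
                     error = function(e) data_error("unreadable profile CSV: ",
                                                    conditionMessage(e)))
    log <- "input: profile CSV (image stages skipped)"
  } else if (!is.null(inp$image)) {
    if (!file.exists(inp$image)) data_error("image not found: ", inp$image)
    img <- tryCatch(read_colony_image(inp$image),
                    error = function(e) data_error("unreadable image: ",
                                                   conditionMessage(e)))
    rb <- inp$roi %||% config_error("image input needs an 'roi' block")
    r <- tryCatch(roi(anchor = unlist(rb$anchor), length = rb$length,
                      width = rb$width, angle = rb$angle %||% 0),
                  error = function(e) config_error("bad roi block: ",
                                                   conditionMessage(e)))
    an <- config$analysis %||% list()
    prof <- profile_from_image(img, r,
                               blur_sigma = pluck_num(an, "blur_sigma", 3),
                               background_sigma = pluck_num(an, "background_sigma",
                                                            r$length / 4))
    log <- "input: image"
  } else {
    config_error("input block needs 'image' or 'profile_csv'")
  }
  list(profile = prof, log = log)
}

#' @rdname run_commands
#' @export
run_analyze <- function(config, out_dir, seed = NULL) {
  config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res_in <- resolve_profile_input(config, out_dir)
  cal <- calibration_from_config(config$calibration %||%
                                   config_error("config needs a 'calibration' block"))
  an <- config$analysis %||% list()
  band <- unlist(an$band %||% c(16, 36))
  res <- analyze_profile(res_in$profile, cal,
                         pad_factor = pluck_num(an, "pad_factor", 8),
                         band = band,
                         snr_threshold = pluck_num(an, "snr_threshold", 10),
                         polarity = an$polarity %||% "dark")
  rings <- res$rings
  utils::write.csv(as.data.frame(rings), file.path(out_dir, "rings.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(res$periodogram),
                   file.path(out_dir, "periodogram.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(period_h = res$estimate$period, snr = res$estimate$snr,
         rhythmic = res$estimate$rhythmic,
         band = band, pad_factor = res$estimate$method_meta$pad_factor,
         rings_per_day = res$rings_per_day),
    file.path(out_dir, "estimate.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  jsonlite::write_json(c(res_in$log, provenance(res$profile)),
                       file.path(out_dir, "provenance.json"))
  echo_config(config, out_dir)
  invisible(res)
}

#' @rdname run_commands
#' @export
run_actogram <- function(config, out_dir, seed = NULL) {
  config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res_in <- resolve_profile_input(config, out_dir)
  cal <- calibration_from_config(config$calibration %||%
                                   config_error("config needs a 'calibration' block"))
  acfg <- config$actogram %||% list()
  sched <- if (!is.null(config$scenario$schedule) || !is.null(acfg$schedule)) {
    schedule_from_config(acfg$schedule %||% config$scenario$schedule)
  }
  acto <- build_actogram(res_in$profile, cal, sched,
                         row_hours = pluck_num(acfg, "row_hours", 48),
                         bin_width = pluck_num(acfg, "bin_width", 0.5))
  write_actogram_csv(acto, file.path(out_dir, "actogram.csv"))
  save_actogram_png(acto, file.path(out_dir, "actogram.png"))
  ps <- NULL
  if (!is.null(acfg$shift_time)) {
    ps <- estimate_phase_shift(res_in$profile, cal,
                               shift_time = acfg$shift_time,
                               period = pluck_num(acfg, "period", 24),
                               skip_transient = pluck_num(acfg, "skip_transient", 72))
    jsonlite::write_json(
      c(as.list(tidy(ps)),
        list(sign_convention = "positive delta = phase delay")),
      file.path(out_dir, "phase_shift.json"), auto_unbox = TRUE, digits = NA)
  }
  echo_config(config, out_dir)
  invisible(list(actogram = acto, phase_shift = ps))
}

#' @rdname run_commands
#' @export
run_compensation <- function(config, out_dir, seed = NULL) {
  config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- config$input %||% config_error("config needs an 'input' block")
  if (is.null(inp$periods_csv)) config_error("input block needs 'periods_csv'")
  if (!file.exists(inp$periods_csv)) {
    data_error("periods CSV not found: ", inp$periods_csv)
  }
  df <- utils::read.csv(inp$periods_csv)
  if (!all(c("temperature_C", "period_h") %in% names(df))) {
    data_error("periods CSV needs columns temperature_C, period_h")
  }
  ref <- unlist(config$reference_pair %||% c(10, 20))
  rep <- compensation_report(df, reference_pair = ref)
  write_compensation_report(rep, file.path(out_dir, "compensation.json"),
                            file.path(out_dir, "compensation_summary.csv"))
  echo_config(config, out_dir)
  invisible(rep)
}
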