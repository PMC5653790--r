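scenario_path <- function(name) {
  system.file("extdata", "scenarios", name, package = "ringclock")
}

test_that("simulate command writes image, truth and profile deterministically", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  res <- run_simulate(scenario_path("dd_245.yaml"), out1)
  expect_true(file.exists(file.path(out1, "colony.png")))
  expect_true(file.exists(file.path(out1, "truth.json")))
  expect_true(file.exists(file.path(out1, "profile.csv")))
  expect_true(file.exists(file.path(out1, "resolved_config.yaml")))
  expect_gte(length(res$truth$ring_times), 5)
  run_simulate(scenario_path("dd_245.yaml"), out2)
  expect_identical(unname(tools::md5sum(file.path(out1, "colony.png"))),
                   unname(tools::md5sum(file.path(out2, "colony.png"))))
})

test_that("the entrain-then-free-run scenario writes six or more rings", {
  out <- withr::local_tempdir()
  res <- run_simulate(scenario_path("ld_dd_20C.yaml"), out)
  expect_gte(length(res$truth$ring_times), 6)
})

test_that("the jet-lag scenario records its shift event in the truth JSON", {
  out <- withr::local_tempdir()
  run_simulate(scenario_path("jetlag_8h.yaml"), out)
  tj <- jsonlite::read_json(file.path(out, "truth.json"),
                            simplifyVector = TRUE)
  expect_equal(tj$schedule$shift_events$time, 96)
  expect_equal(tj$schedule$shift_events$delay, 8)
})

test_that("analyze command recovers the period from simulated outputs", {
  sim_dir <- withr::local_tempdir()
  run_simulate(scenario_path("dd_245.yaml"), sim_dir)
  out <- withr::local_tempdir()
  cfg <- list(input = list(profile_csv = file.path(sim_dir, "profile.csv")),
              calibration = list(truth_json = file.path(sim_dir, "truth.json")))
  run_analyze(cfg, out)
  est <- jsonlite::read_json(file.path(out, "estimate.json"),
                             simplifyVector = TRUE)
  expect_lt(abs(est$period_h - 24.5), 0.5)
  expect_true(est$rhythmic)
  expect_true(file.exists(file.path(out, "rings.csv")))
  expect_true(file.exists(file.path(out, "periodogram.csv")))
  prov <- unlist(jsonlite::read_json(file.path(out, "provenance.json")))
  expect_match(prov[1], "image stages skipped")
})

test_that("analyze routes image input through the full chain", {
  sim_dir <- withr::local_tempdir()
  sim <- run_simulate(scenario_path("dd_245.yaml"), sim_dir)
  r <- ringclock:::default_roi(sim$truth)
  out <- withr::local_tempdir()
  cfg <- list(
    input = list(image = file.path(sim_dir, "colony.png"),
                 roi = list(anchor = as.list(r$anchor), length = r$length,
                            width = r$width, angle = 0)),
    calibration = list(anchor_a = list(30, 12.25),
                       anchor_b = list(30 + 2.5 * 5 * 24.5, 12.25 + 5 * 24.5)))
  run_analyze(cfg, out)
  est <- jsonlite::read_json(file.path(out, "estimate.json"),
                             simplifyVector = TRUE)
  expect_lt(abs(est$period_h - 24.5), 0.5)
})

test_that("config and data errors carry their condition classes", {
  out <- withr::local_tempdir()
  expect_error(run_analyze(list(), out), class = "ringclock_config_error")
  expect_error(run_analyze(list(input = list(profile_csv = "/missing.csv"),
                                calibration = list()), out),
               class = "ringclock_data_error")
  bad <- withr::local_tempfile(fileext = ".png")
  writeLines("not a png", bad)
  expect_error(
    run_analyze(list(input = list(image = bad,
                                  roi = list(anchor = list(0, 0),
                                             length = 40, width = 8)),
                     calibration = list(anchor_a = list(0, 0),
                                        anchor_b = list(10, 10))), out),
    class = "ringclock_data_error")
  expect_error(run_compensation(list(), out),
               class = "ringclock_config_error")
})

test_that("actogram command writes the raster and the phase-shift estimate", {
  sim_dir <- withr::local_tempdir()
  run_simulate(scenario_path("jetlag_8h.yaml"), sim_dir)
  out <- withr::local_tempdir()
  cfg <- yaml::read_yaml(scenario_path("jetlag_8h.yaml"))
  cfg$input <- list(profile_csv = file.path(sim_dir, "profile.csv"))
  cfg$calibration <- list(truth_json = file.path(sim_dir, "truth.json"))
  run_actogram(cfg, out)
  expect_true(file.exists(file.path(out, "actogram.csv")))
  expect_true(file.exists(file.path(out, "actogram.png")))
  ps <- jsonlite::read_json(file.path(out, "phase_shift.json"),
                            simplifyVector = TRUE)
  expect_lt(abs(ps$delta_h - 8), 0.5)
  # without a shift_time the command produces the actogram only
  cfg$actogram$shift_time <- NULL
  out2 <- withr::local_tempdir()
  run_actogram(cfg, out2)
  expect_false(file.exists(file.path(out2, "phase_shift.json")))
})

test_that("compensation command turns a period table into the report", {
  out <- withr::local_tempdir()
  csv <- withr::local_tempfile(fileext = ".csv")
  set.seed(23)
  # plate-to-plate scatter comparable to the group differences, so the
  # compensated clock is not flagged by the ANOVA
  df <- data.frame(
    temperature_C = rep(c(10, 14, 20), each = 3),
    plate_id = paste0("p", 1:9),
    period_h = c(25.5, 26.8, 28.1, 23.1, 24.4, 25.7, 23.0, 24.5, 26.0))
  utils::write.csv(df, csv, row.names = FALSE)
  run_compensation(list(input = list(periods_csv = csv)), out)
  rep <- jsonlite::read_json(file.path(out, "compensation.json"),
                             simplifyVector = TRUE)
  expect_equal(rep$q10_display, 1.1)
  expect_gt(rep$anova$p_value, 0.05)
  expect_true(file.exists(file.path(out, "compensation_summary.csv")))
})
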