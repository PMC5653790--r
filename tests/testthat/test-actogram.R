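make_calibrated_series <- function(duration = 144, period = 24,
                                   noise = 0, seed = 1, phase = 12) {
  # bare cosine "band signal" sampled at 2.5 px/h, dark bands at `phase`
  set.seed(seed)
  x <- 0:(floor(2.5 * duration) - 1)
  t_h <- x / 2.5
  y <- -cos(2 * pi * (t_h - phase) / period) + rnorm(length(x), 0, noise)
  list(profile = bare_profile(y, x), calibration = bare_calibration(2.5, 0),
       t_h = t_h)
}

test_that("a six-day record yields five exactly double-plotted rows", {
  s <- make_calibrated_series(144)
  acto <- build_actogram(s$profile, s$calibration, light_schedule())
  expect_equal(nrow(acto$rows), 5)
  nb <- ncol(acto$rows)
  for (r in 1:(nrow(acto$rows) - 1)) {
    expect_identical(acto$rows[r, (nb / 2 + 1):nb],
                     acto$rows[r + 1, 1:(nb / 2)])
  }
})

test_that("constant signals give constant actogram rows", {
  prof <- bare_profile(rep(4, 360))
  acto <- build_actogram(prof, bare_calibration(2.5, 0), NULL,
                         detrend = FALSE)
  vals <- acto$rows[!is.na(acto$rows)]
  expect_true(all(abs(vals - 4) < 1e-9))
})

test_that("entrained rhythms align vertically across actogram rows", {
  sim <- simulate_colony(light_schedule(), clock_params(),
                         colony_model(duration = 144), seed = 3)
  prof <- profile_from_image(sim$image, ringclock:::default_roi(sim$truth))
  cal <- calibrate_from_truth(sim$truth, sim$truth$colony$start_radius)
  acto <- build_actogram(prof, cal, light_schedule())
  # per-row position of the first-half band trough (dark rings)
  nb <- ncol(acto$rows)
  peak_h <- apply(acto$rows[, 1:(nb / 2)], 1, function(v) {
    (which.min(v) - 0.5) * acto$bin_width
  })
  # circular SD below 1 h across rows
  rad <- 2 * pi * peak_h / 24
  R <- sqrt(mean(cos(rad))^2 + mean(sin(rad))^2)
  circ_sd_h <- sqrt(-2 * log(R)) * 24 / (2 * pi)
  expect_lt(circ_sd_h, 1)
})

test_that("light marks follow the schedule through a shift", {
  s <- make_calibrated_series(240)
  sched <- light_schedule(shift_events = data.frame(time = 96, delay = 8))
  acto <- build_actogram(s$profile, s$calibration, sched)
  m <- acto$light_marks
  expect_true(nrow(m) > 0)
  # after the delay the within-row onset moves from 0/24 to 8/32
  late <- m[m$row >= 6, ]
  expect_true(all(late$onset %in% c(8, 32) | late$onset == 0))
})

test_that("records shorter than a row or two days are rejected", {
  s <- make_calibrated_series(40)
  expect_error(build_actogram(s$profile, s$calibration, NULL),
               "two days")
})

test_that("phase-shift estimation recovers synthetic delays, advances and null shifts", {
  # pure series with a hard phase step (no relaxation): the estimator alone
  mk <- function(delta) {
    x <- 0:599; t_h <- x / 2.5
    ph <- ifelse(t_h < 96, 12, 12 + delta)
    y <- -cos(2 * pi * (t_h - ph) / 24) + rnorm(600, 0, 0.05)
    bare_profile(y, x)
  }
  set.seed(7)
  for (d in c(0, 8, -4)) {
    ps <- estimate_phase_shift(mk(d), bare_calibration(2.5, 0),
                               shift_time = 96, period = 24)
    expect_equal(ps$delta, d, tolerance = 0.2)
  }
})

test_that("the phase-shift estimator is equivariant under extra post-segment shifts", {
  set.seed(8)
  x <- 0:599; t_h <- x / 2.5
  base <- function(s) {
    ph <- ifelse(t_h < 96, 12, 12 + 3 + s)
    bare_profile(-cos(2 * pi * (t_h - ph) / 24), x)
  }
  d0 <- estimate_phase_shift(base(0), bare_calibration(2.5, 0), 96, 24)$delta
  for (s in c(2, 5, -3)) {
    ds <- estimate_phase_shift(base(s), bare_calibration(2.5, 0), 96, 24)$delta
    # exact equivariance holds in the continuum; discrete sampling over a
    # non-integer number of cycles leaves a <0.1 h wobble
    expect_lt(abs(ringclock:::wrap_signed(ds - d0 - s, 24)), 0.1)
  }
})

test_that("phase uncertainty shrinks roughly like 1/sqrt(days fitted)", {
  # scale both segments by m: 4x the data should halve the uncertainty
  est_unc <- function(m) {
    pre_h <- 96 * m; post_h <- 72 * m
    x <- 0:(floor(2.5 * (pre_h + 72 + post_h)) - 1)
    t_h <- x / 2.5
    set.seed(9)
    y <- -cos(2 * pi * (t_h - 12) / 24) + rnorm(length(x), 0, 0.3)
    estimate_phase_shift(bare_profile(y, x), bare_calibration(2.5, 0),
                         shift_time = pre_h, period = 24)$uncertainty
  }
  u <- vapply(c(1, 4), est_unc, numeric(1))
  expect_gt(u[1] / u[2], 1.6)   # ~2 expected from 4x the data
})

test_that("insufficient data on either side of the shift is an error", {
  s <- make_calibrated_series(144)
  expect_error(estimate_phase_shift(s$profile, s$calibration,
                                    shift_time = 20, period = 24),
               "before the shift")
  expect_error(estimate_phase_shift(s$profile, s$calibration,
                                    shift_time = 100, period = 24),
               "after the transient")
})

test_that("jet-lag colonies read out the programmed 8 h delay", {
  j <- jetlag_study(n_seeds = 2, base_seed = 5)
  expect_true(all(abs(j$delta_h - 8) < 0.5))
})

test_that("actogram CSV export writes one row per day", {
  s <- make_calibrated_series(144)
  acto <- build_actogram(s$profile, s$calibration, NULL)
  path <- withr::local_tempfile(fileext = ".csv")
  write_actogram_csv(acto, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), nrow(acto$rows))
  expect_equal(ncol(df), ncol(acto$rows) + 1)
})
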