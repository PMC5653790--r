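test_that("calibration arithmetic, symmetry and failure modes", {
  cal <- calibrate(c(100, 0), c(820, 144))
  expect_equal(cal$px_per_h, 5)
  expect_equal(cal$pos_to_time(460), 72)
  expect_equal(cal$time_to_pos(72), 460)
  swapped <- calibrate(c(820, 144), c(100, 0))
  expect_equal(swapped$px_per_h, cal$px_per_h)
  expect_equal(swapped$pos_to_time(460), 72)
  expect_error(calibrate(c(0, 5), c(10, 5)), "times")
  expect_error(calibrate(c(5, 0), c(5, 10)), "positions")
})

test_that("truth-anchored calibration recovers the growth rate exactly", {
  tr <- dd_truth(period = 26.8, duration = 150)
  cal <- calibrate_from_truth(tr)
  expect_equal(cal$px_per_h, tr$colony$growth_rate, tolerance = 1e-12)
  cal2 <- calibrate_from_truth(tr, origin_px = 20)
  expect_equal(cal2$pos_to_time(tr$ring_radii[1] - 20), tr$ring_times[1])
})

test_that("quadratic detrending matches the normal-equations oracle", {
  x <- 0:199
  y <- 3 + 0.2 * x - 0.001 * x^2 + 5 * cos(2 * pi * x / 60)
  prof <- bare_profile(y, x)
  res <- detrend_quadratic(prof)$intensity
  # independent brute-force least squares via the normal equations
  X <- cbind(1, x, x^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(res, as.numeric(y - X %*% beta), tolerance = 1e-8)
  # residual orthogonal to the quadratic basis
  for (k in 0:2) {
    expect_lt(abs(sum(res * x^k)) / (sqrt(sum(res^2)) * sqrt(sum(x^(2 * k)))),
              1e-8)
  }
})

test_that("detrending is exact on polynomials and idempotent", {
  x <- 0:99
  quad <- bare_profile(7 - 0.3 * x + 0.002 * x^2, x)
  expect_lt(max(abs(detrend_quadratic(quad)$intensity)), 1e-9 * 7)
  expect_lt(max(abs(detrend_quadratic(bare_profile(rep(5, 50)))$intensity)),
            1e-12)
  set.seed(5)
  noisy <- bare_profile(rnorm(100), x)
  once <- detrend_quadratic(noisy)
  twice <- detrend_quadratic(once)
  expect_equal(twice$intensity, once$intensity, tolerance = 1e-10)
})

test_that("periodogram pinpoints a pure cosine and satisfies Parseval", {
  cal <- bare_calibration(px_per_h = 2.5, origin_px = 0)
  x <- 0:359                       # 144 h at 2.5 px/h
  t_h <- x / 2.5
  prof <- bare_profile(cos(2 * pi * t_h / 24), x)
  pg <- compute_periodogram(prof, cal, pad_factor = 8)
  f_peak <- pg$freq_per_h[which.max(pg$power)]
  df <- pg$freq_per_h[2] - pg$freq_per_h[1]
  expect_lt(abs(f_peak - 1 / 24), df + 1e-12)
  # Parseval: one-sided power sums to N * population variance of the
  # mean-removed residual (= its sum of squares)
  xr <- detrend_quadratic(prof)$intensity
  xr <- xr - mean(xr)
  expect_equal(sum(pg$power), length(xr) * mean(xr^2), tolerance = 1e-6)
  # null signal: essentially zero power everywhere
  pg0 <- compute_periodogram(bare_profile(rep(0, 360), x), cal)
  expect_lt(max(pg0$power), 1e-20)
  expect_error(compute_periodogram(prof, cal, pad_factor = 0), "pad_factor")
})

test_that("an exactly on-bin sinusoid is estimated at the bin period", {
  # choose N and period so the frequency falls on a padded bin AND the
  # parabolic refinement sees a symmetric peak: 360 samples, 45-bin period
  cal <- bare_calibration(2.5, 0)
  x <- 0:359
  prof <- bare_profile(sin(2 * pi * x / 60), x)  # period 24 h at 2.5 px/h
  pg <- compute_periodogram(prof, cal, pad_factor = 8)
  # the raw peak bin is exactly the true frequency bin
  expect_equal(pg$freq_per_h[which.max(pg$power)], 1 / 24, tolerance = 1e-12)
  # log-parabolic refinement moves it by less than half a padded bin
  est <- estimate_period(pg)
  expect_equal(est$period, 24, tolerance = 0.25 / 24)
  expect_true(est$rhythmic)
})

test_that("period recovery from a generated DD profile lands within half an hour", {
  for (P in c(22.3, 24.5, 26.8)) {
    tr <- dd_truth(period = P)
    prof <- render_profile(tr, seed = 17)
    est <- estimate_period(
      compute_periodogram(prof, calibrate_from_truth(tr)))
    expect_lt(abs(est$period - P), 0.5)
    expect_true(est$rhythmic)
  }
})

test_that("white-noise profiles are called non-rhythmic at the calibrated threshold", {
  cal <- bare_calibration(2.5, 0)
  calls <- vapply(1:200, function(s) {
    set.seed(s)
    prof <- bare_profile(rnorm(360, 0, 5))
    estimate_period(compute_periodogram(prof, cal))$rhythmic
  }, logical(1))
  expect_gte(mean(!calls), 0.95)
})

test_that("ring detection recovers all rings of a clean profile and none of a constant", {
  tr <- dd_truth()
  prof <- render_profile(tr, noise_sd = 0)
  cal <- calibrate_from_truth(tr)
  rings <- detect_rings(prof, calibration = cal)
  expect_equal(nrow(rings), length(tr$ring_radii))
  expect_true(all(abs(rings$position_px - tr$ring_radii) <= 1))
  expect_equal(nrow(detect_rings(bare_profile(rep(3, 100)))), 0)
})

test_that("bright-polarity rings are found with the polarity flag", {
  tr <- dd_truth(ring_polarity = "bright")
  prof <- render_profile(tr, noise_sd = 0)
  rings <- detect_rings(prof, polarity = "bright",
                        calibration = calibrate_from_truth(tr))
  expect_equal(nrow(rings), length(tr$ring_radii))
})

test_that("rings_per_day arithmetic and degenerate cases", {
  rings <- tibble::tibble(position_px = seq(50, 350, by = 60),
                          prominence = 1,
                          time_h = seq(0, 120, by = 24))
  expect_equal(rings_per_day(rings), 1.0)
  expect_message(r1 <- rings_per_day(rings[1, ]), "fewer than two")
  expect_true(is.na(r1))
  # DD at 26.8 h: one ring per 26.8 h is 24/26.8 rings per day
  tr <- dd_truth(period = 26.8, duration = 160.8)
  prof <- render_profile(tr, seed = 23)
  rings2 <- detect_rings(prof, calibration = calibrate_from_truth(tr),
                         expected_period = 26.8)
  expect_equal(rings_per_day(rings2), 24 / 26.8, tolerance = 0.05)
})

test_that("period in hours is invariant to the pixel scale of growth", {
  est <- purrr::map_dbl(c(2.5, 5), function(v) {
    tr <- dd_truth(period = 24.5, growth_rate = v)
    prof <- render_profile(tr, seed = 31)
    estimate_period(compute_periodogram(prof, calibrate_from_truth(tr)))$period
  })
  # within one padded bin (~0.5 h near 24.5 on a 6-day record)
  expect_lt(abs(est[1] - est[2]), 0.5)
})

test_that("the periodogram peak ignores any quadratic trend added upstream", {
  tr <- dd_truth()
  prof <- render_profile(tr, seed = 37)
  cal <- calibrate_from_truth(tr)
  p1 <- estimate_period(compute_periodogram(prof, cal))$period
  trended <- prof
  trended$intensity <- trended$intensity + 40 - 0.5 * trended$position_px +
    8e-4 * trended$position_px^2
  attr(trended, "provenance") <- character()  # force a fresh detrend
  p2 <- estimate_period(compute_periodogram(trended, cal))$period
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("estimates stay within half an hour across the circadian period range", {
  # end-to-end recovery property at the profile level across P in 22..30 h
  set.seed(41)
  cases <- tibble::tibble(P = seq(22, 30, length.out = 25),
                          seed = sample.int(1e6, 25))
  err <- purrr::pmap_dbl(cases, function(P, seed) {
    tr <- dd_truth(period = P)
    prof <- render_profile(tr, seed = seed)
    gradient <- 1 + 0.1 * (prof$position_px / max(prof$position_px) - 0.5)
    prof$intensity <- prof$intensity * gradient
    corrected <- pseudo_flat_field(prof$intensity, length(prof$intensity) / 4)
    prof$intensity <- as.numeric(corrected)
    est <- estimate_period(compute_periodogram(prof, calibrate_from_truth(tr)))
    abs(est$period - P)
  })
  expect_gte(mean(err <= 0.5), 0.9)
})
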