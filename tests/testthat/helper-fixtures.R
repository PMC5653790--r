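# Shared fixture builders. Everything is generated in code; sizes are kept
# small so individual tests stay fast, while acceptance tests use the
# package defaults.

dd_truth <- function(period = 24.5, duration = 144, growth_rate = 2.5,
                     ...) {
  synthetic_truth(light_schedule(dd_start = 0),
                  clock_params(free_running_period = period),
                  colony_model(growth_rate = growth_rate,
                               duration = duration, ...))
}

ld_truth <- function(duration = 144, growth_rate = 2.5, ...) {
  synthetic_truth(light_schedule(),
                  clock_params(),
                  colony_model(growth_rate = growth_rate,
                               duration = duration, ...))
}

# small noise-free colony image for geometry tests
small_colony_sim <- function(duration = 96, noise_sd = 0, seed = 1,
                             illumination = illumination_field("uniform")) {
  simulate_colony(light_schedule(dd_start = 0), clock_params(24.5),
                  colony_model(duration = duration),
                  illumination = illumination,
                  noise_sd = noise_sd, seed = seed)
}

# uniform-pixel calibration used when tests build bare profiles directly:
# pos 20 px <-> 0 h at 2.5 px/h (the default generator geometry)
bare_calibration <- function(px_per_h = 2.5, origin_px = 20) {
  calibrate(c(origin_px, 0), c(origin_px + px_per_h * 100, 100))
}

bare_profile <- function(intensity, position = seq_along(intensity) - 1) {
  as_radial_profile(data.frame(position_px = position,
                               intensity = intensity))
}

# brute-force sums-of-squares one-way ANOVA, the independent oracle the
# anova_periods() implementation is checked against
ss_anova_oracle <- function(groups) {
  all_x <- unlist(groups)
  gm <- mean(all_x)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- length(groups) - 1
  dfw <- length(all_x) - length(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(F = f, p = stats::pf(f, dfb, dfw, lower.tail = FALSE))
}
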