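# ringclock

Circadian analysis of concentric growth rings in fungal colonies.

Fungal colonies growing on solid media can deposit one concentric ring per
circadian cycle. Because radial growth is constant, a single end-point
photograph encodes a multi-day time series: ring spacing measures the
clock's period, ring phase its entrainment state, and the period's
constancy across incubation temperatures its temperature compensation.
`ringclock` is for chronobiologists and image analysts who want to turn
such photographs — or 1-D band-intensity profiles — into period estimates,
actograms and Q10 summaries, with a fully seeded synthetic colony
generator so that every stage of the pipeline can be validated against
known ground truth.

## The method

Given a grayscale colony photograph:

1. extract a rectangular region running radially from the seed, with ring
   bands parallel to its short side (bilinear sampling, any angle);
2. smooth with a Gaussian filter (σ = 3 px) and remove uneven
   illumination with a pseudo flat-field correction (divide by a heavy
   blur of the patch, rescale by its mean);
3. average each row of pixels sharing a radial coordinate into a 1-D
   intensity profile *I(x)*;
4. calibrate pixels to hours from two anchor events (by default the first
   and last ring): px/h = Δposition / Δtime;
5. subtract the best-fitting quadratic trend and compute the zero-padded
   DFT periodogram of the residual; the in-band (16–36 h) peak, refined by
   parabolic interpolation on log power, gives the free-running period
   *P*; the peak-to-median in-band power ratio gives a rhythmicity call;
6. detect individual rings as prominent local extrema (rings per day =
   (count − 1)/span × 24), build double-plotted actograms, and estimate
   jet-lag phase shifts by fitting the phase of a cosine at the entraining
   period before and after the schedule change;
7. compare periods across temperatures:
   Q10 = (P_low / P_high)^(10/ΔT) on group means, plus a one-way ANOVA
   across temperature groups.

The synthetic generator inverts the measurement: a clock phase advancing
at 1/24 h⁻¹ under entrainment and 1/P in darkness (with exponential
re-entrainment after schedule shifts) drives ring deposition; constant
radial growth maps ring times to radii; raised-cosine bands, a planar or
vignette illumination field, Gaussian camera noise and 8/16-bit
quantization produce the image, alongside the exact ground truth.

## A worked example

Simulate a six-day colony free-running in constant darkness at a true
period of 24.5 h, then recover that period through the full image
pipeline:

```r
library(ringclock)

sim <- simulate_colony(
  schedule = light_schedule(dd_start = 0),        # constant darkness
  clock    = clock_params(free_running_period = 24.5),
  colony   = colony_model(duration = 144),        # six days at 2.5 px/h
  seed     = 101)
sim$truth
#> <synthetic_truth> 6 rings over 144 h, FRP 24.5 h, 2.5 px/h

cal <- calibrate_from_truth(sim$truth, sim$truth$colony$start_radius)
r   <- roi(anchor = sim$truth$colony$seed_center + c(20, -7.5),
           length = 358, width = 16)
res <- analyze_colony_image(sim$image, r, cal)

res$estimate
#> <period_estimate> 24.41 h (SNR 30.0, rhythmic)
tidy(res$estimate)
#> # A tibble: 1 × 4
#>   period_h peak_power   snr rhythmic
#>      <dbl>      <dbl> <dbl> <lgl>
#> 1     24.4     34811.  30.0 TRUE
nrow(res$rings); res$rings_per_day
#> 6
#> 0.98
```

The estimate lands within 0.1 h of the programmed 24.5 h period; all six
rings are found, at just under one ring per free-running cycle per day.
`autoplot(res$periodogram, estimate = res$estimate)` draws the
periodogram, `autoplot(build_actogram(res$profile, cal, sim$truth$schedule))`
the double-plotted actogram.

Temperature compensation from per-plate period estimates:

```r
rep <- compensation_report(list(`10` = c(25.5, 26.8, 28.1),
                                `14` = c(23.1, 24.4, 25.7),
                                `20` = c(23.0, 24.5, 26.0)))
rep
#> # A tibble: 3 × 5
#>   temperature_C     n mean_h  sd_h sem_h
#> 1            10     3   26.8  1.3  0.751
#> 2            14     3   24.4  1.30 0.751
#> 3            20     3   24.5  1.5  0.866
#> Q10(10-20 C) = 1.094 (1.1 at one decimal)
#> one-way ANOVA: F(2, 6) = 2.947, p = 0.128
```

A Q10 near 1 with no significant period difference across 10–20 °C is the
signature of a temperature-compensated circadian clock.

Config-driven runs (`run_simulate()`, `run_analyze()`, `run_actogram()`,
`run_compensation()`) accept YAML configs — see the bundled scenarios in
`inst/extdata/scenarios/` — and a thin command-line shim ships in
`inst/scripts/ringclock`.

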