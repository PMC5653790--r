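---
title: "Quantifying circadian rhythms in colony ring patterns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying circadian rhythms in colony ring patterns: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 3.5)
library(ringclock)
```

Many fungi growing on solid media deposit one concentric ring per circadian
cycle. Because radial growth is constant, the radial position of a ring is a
linear proxy for the time it was laid down, so a single end-point photograph
of a colony encodes a multi-day time series: ring spacing gives the period,
ring phase gives entrainment state, and comparing periods across incubation
temperatures measures temperature compensation. `ringclock` implements that
reading, end to end, together with a synthetic colony generator that makes
every stage testable against known ground truth.

## The clock and growth model behind the generator

The generator treats the colony as a clock-driven printer.

**Phase dynamics.** A dimensionless clock phase $\phi(t)$ (in cycles)
advances at $1/T_{zg}$ per hour while the culture is entrained to a
light-dark (LD) cycle of length $T_{zg}$ (default 24 h, 12:12), and at
$1/P$ after transfer to constant darkness (DD), where $P$ is the
free-running period (FRP). An abrupt schedule shift by $d$ hours (a
"jet-lag" event; delays positive) moves the entrainment target by
$-d/T_{zg}$ cycles; the realized phase stays continuous and relaxes onto
the new target as $\exp(-t/\tau)$. The relaxation constant $\tau$
(default 36 h) is our modelling choice — end-point photographs constrain
the transient only loosely ("a longer period for a few days, then
stable"), so the functional form is exponential, the simplest phase-only
relaxation, and $\tau$ is an explicit parameter rather than an assumption.
In the limit $\tau \to 0$ the post-shift pattern is exactly the pre-shift
pattern translated by $d$; the test suite checks that limit.

**Ring deposition.** One ring is deposited each time $\phi$ crosses the
deposition phase, which defaults to dark onset (the phase of ring
formation is not observable in end-point images; the default is a
convention, exposed as `entrained_phase`). Deposition uses the *first*
upward crossing of each phase level, so an instantaneous delay — which
steps the realized phase backwards — cannot deposit the same ring twice.

**Optics.** Radius maps to time through the constant growth rate $v$
(default 2.5 px/h). Band intensity follows a raised cosine of phase,
sharpened by an exponent (default 2); the paper-level literature does not
define a band waveform, so this choice is declared, not inferred. Ring
polarity is a flag (`dark` by default — pigmented rings darker than
inter-ring zones) because grayscale polarity is likewise a property of the
imaging setup, not of the clock. Images are multiplied by an illumination
field (default: planar gradient spanning ±10% across the frame), Gaussian
camera noise is added (default SD 2% of the 8-bit range), and intensities
are quantized by rounding. All randomness flows from one integer seed per
call; identical configurations and seeds give bit-identical images.

What the generator deliberately does *not* emulate: hyphal texture,
3-D colony relief, temperature-dependent growth rate (temperature enters
only as metadata and as the per-run choice of $P$), condensation and other
plate artifacts, or non-Gaussian sensor noise. Passing recovery tests on
these images therefore demonstrates that the *pipeline* is correct and
unbiased under its stated assumptions — constant growth, multiplicative
smooth illumination, additive noise — not that those assumptions hold for
any particular laboratory's photographs.

## The measurement pipeline

The preprocessing chain mirrors standard practice for banded colonies:

1. **ROI extraction.** A user-chosen rectangle extending radially from the
   seed toward the colony border, sampled with bilinear interpolation at
   any rotation angle. Rings must be approximately parallel to the short
   side; because rings are concentric this bounds the usable width — across
   a rectangle of width $w$ the transverse average smears band positions
   inward by roughly $w^2/(24\,r)$ pixels at radius $r$. The bundled
   defaults use $w = 16$ px, which keeps the smear below 0.1 px beyond the
   innermost rings at the default geometry.
2. **Gaussian smoothing**, $\sigma = 3$ px, separable convolution with
   reflective boundaries ($\sigma = 0$ is the identity).
3. **Pseudo flat-field correction**: divide by a heavily blurred copy of
   the patch and rescale by the blurred copy's mean. The background sigma
   defaults to a quarter of the ROI length and should be much larger than
   the ring spacing (the function warns below 5× spacing). The exact
   flat-field formula used by interactive image tools varies; ours is the
   common divide-by-blur idiom and is recorded in the provenance log.
4. **Collapse**: average all pixels sharing a radial coordinate, giving
   intensity versus radial position.

Every stage appends to a provenance log carried by the profile, so the
order of operations is auditable downstream.

**Calibration.** Two anchor events of known time convert pixels to hours:
by default the first and the last ring (pixel distance divided by elapsed
hours), but any pair of anchors — e.g. a known LD→DD transfer mark — is
accepted, since ring formation times are not directly observable in DD.

**Detrending and spectrum.** The best-fitting quadratic in position is
subtracted (residual orthogonal to $\{1, x, x^2\}$; idempotent), the
residual is mean-removed, zero-padded eightfold, and its magnitude-squared
DFT gives the periodogram, normalized so the one-sided power sums to
$N \cdot \mathrm{var}$. A rectangular window is the default; a Hann window
is available behind a flag. The in-band ($16$–$36$ h) peak is refined by
three-point parabolic interpolation on log power. On a six-day record the
raw padded bin is ~0.5 h near 24 h; interpolation brings recovery error to
~0.1 h. The band was chosen to cover reported fungal FRPs (down to ~22 h
and beyond 30 h for long-period species) while excluding detrending
leakage; both ends are parameters.

**Rhythmicity call.** SNR = peak power / median in-band power, with a
default threshold of 10. The threshold was calibrated once on the simulated
null (200 pure-noise profiles at the default record length): a six-day
record yields only ~5 independent in-band frequency bins, so the null
distribution of this SNR is heavy-tailed (95th percentile ≈ 9) and small
thresholds would flag a large fraction of noise records as rhythmic.
At 10 the measured null false-positive rate is ~2.5%, while genuine
synthetic colonies score SNR ≈ 30 or higher.

**Ring detection** finds local maxima (after polarity normalization and
detrending) with topographic prominence at least 0.5× the profile SD,
separated by at least half the expected ring spacing. The prominence
criterion assumes a ring signal is present — it is a *localization* tool;
deciding *whether* a rhythm exists is the periodogram's job, which is why
the SNR call, not the ring count, guards against no-signal profiles.

**Ring rate** is (count − 1)/(time span first→last ring) × 24, the
quantity that reads "one ring per day" under entrainment.

## Actograms and jet-lag analysis

`build_actogram()` resamples the calibrated profile onto 0.5 h bins and
stacks one row per day, each spanning 48 h, so the right half of each row
repeats as the left half of the next (exactly, by construction — the bins
are shared). Light onset/offset marks follow the schedule through shift
events. Rows whose first 24 h lie inside the record are kept; the trailing
half of the last row may be NA-padded.

The phase shift around a schedule change is estimated by fitting the phase
of a cosine at the entraining period separately to the pre-shift segment
and to the post-shift segment after skipping a 72 h re-entrainment
transient ("a few days"), then reporting their circular difference, delays
positive. Uncertainty comes from the fit covariance by the delta method.
Two properties of this estimator are worth stating plainly:

- With exponential re-entrainment ($\tau = 36$ h) the rhythm has not fully
  converged when the post-fit window opens: averaged over a 3-day-skip,
  6-days-post protocol, ~0.4 h of the nominal 8 h delay is still
  unexpressed, so the estimator converges to ~7.6 h, not 8.0. This is a
  property of the transient, not an estimator bias — the no-shift control
  reads 0.0–0.1 h.
- Both segments share the ring polarity, so the estimate is
  polarity-invariant.

## Temperature compensation

`q10()` uses the rate convention $Q_{10} = (P_{low}/P_{high})^{10/\Delta T}$
(rates are $1/P$), computed on group-mean periods; with measured means of
26.8 h at 10 °C and 24.5 h at 20 °C this gives 1.09, i.e. 1.1 at one
decimal — a temperature-compensated clock, far from the 2–3 typical of
uncompensated biochemical rates. Both full precision and a one-decimal
display value are reported. `compensation_report()` adds per-temperature
means, SDs and SEMs (both spread conventions are emitted; neither is
guessed to be the canonical one) and a classical one-way fixed-effects
ANOVA across temperatures (`stats::oneway.test`, equal variances), with a
degenerate-variance flag instead of an error when all plates agree
exactly. Q10 is computed on group means because plates are not paired
across temperatures.

## Numerical and design notes

- Coordinates are 0-based pixel centres; the radial axis increases away
  from the seed; RGB images collapse by Rec. 601 luminance.
- The parabolic peak refinement clamps to ±0.5 bin and falls back to the
  raw bin at grid edges or zero-power neighbours.
- Circular differences wrap to $(-P/2, P/2]$.
- Degenerate inputs are first-class: zero rings is a valid detection
  result, fewer than two rings makes the ring rate `NA` with a message,
  all-zero patches are rejected by the flat-field stage, and sub-cycle
  records yield an empty ring-time vector.
- Problem sizes in the validation studies — six-day colonies at 2.5 px/h
  (≈820 px images), 50 replicate seeds for period recovery, 20 for the
  jet-lag study, 200 null profiles for the SNR calibration, 1000
  replicates for the ANOVA type-I check — were chosen so each study gives
  stable medians and rates while a full validation run completes in about
  a minute.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_colony(
  schedule = light_schedule(dd_start = 0),       # DD from the start
  clock    = clock_params(free_running_period = 24.5),
  colony   = colony_model(duration = 144),       # six days
  seed     = 101)

cal <- calibrate_from_truth(sim$truth, sim$truth$colony$start_radius)
res <- analyze_colony_image(sim$image, ringclock:::default_roi(sim$truth), cal)

tidy(res$estimate)        # period_h ~ 24.4-24.6, rhythmic TRUE
autoplot(res$periodogram, estimate = res$estimate)
```

## Known limitations

- Periods are estimated from a single ROI; multi-ROI averaging and
  alternative spectral estimators (Lomb–Scargle, wavelets, chi-square
  periodograms) are out of scope.
- The phase-shift estimator assumes the entraining period is known and
  constant on both sides of the shift.
- The generator's truth anchors make calibration exact; with real images
  the first/last-ring rule inherits the analyst's ring-time assignments,
  and calibration error propagates multiplicatively into the period.
- Very wide ROIs violate the parallel-band assumption near the colony
  centre (see the width bound above); the package does not currently
  correct for band curvature.
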