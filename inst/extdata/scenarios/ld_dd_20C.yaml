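# 12:12 LD entrainment for two days, then constant darkness at 20 C:
# free-running banding at the 20 C free-running period.
scenario:
  schedule:
    cycle_length: 24
    light_fraction: 0.5
    phase_offset: 0
    dd_start: 48
  clock:
    free_running_period: 24.5
    entrained_phase: 0
    relaxation_tau: 36
  colony:
    growth_rate: 2.5
    start_radius: 20
    duration: 192
    baseline_intensity: 180
    ring_amplitude: 80
    ring_sharpness: 2
    ring_polarity: dark
  illumination:
    kind: planar
    gradient: 0.2
  noise_sd: 5.1
  seed: 1
  temperature_C: 20
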