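# Constant darkness from the start, free-running period 24.5 h (the 20 C
# free-running conditions), six days of growth.
scenario:
  schedule:
    cycle_length: 24
    light_fraction: 0.5
    phase_offset: 0
    dd_start: 0
  clock:
    free_running_period: 24.5
    entrained_phase: 0
    relaxation_tau: 36
  colony:
    growth_rate: 2.5
    start_radius: 20
    duration: 144
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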