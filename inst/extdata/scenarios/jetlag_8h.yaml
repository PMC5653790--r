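# Jet-lag protocol: four days of 12:12 LD entrainment, then an 8 h delay
# of the light-dark cycle, followed by six more days under the delayed
# schedule. Phase re-entrains with a 36 h time constant.
scenario:
  schedule:
    cycle_length: 24
    light_fraction: 0.5
    phase_offset: 0
    shift_events:
      - time: 96
        delay: 8
  clock:
    free_running_period: 24.5
    entrained_phase: 0
    relaxation_tau: 36
  colony:
    growth_rate: 2.5
    start_radius: 20
    duration: 240
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
actogram:
  shift_time: 96
  period: 24
  skip_transient: 72
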