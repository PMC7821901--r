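{
  "duration_s": 60,
  "behavior_rate_hz": 20,
  "calcium_rate_hz": 20,
  "bout_duration_s": {
    "mean": 3,
    "min": 1.5,
    "max": 6
  },
  "immobility_duration_s": {
    "mean": 4,
    "min": 3.2,
    "max": 8
  },
  "grooming_prob": 1,
  "p_bout": 1,
  "run_speed_cms": 15,
  "noise_sd": 0.05,
  "kernel_rise_s": 0.075,
  "kernel_decay_s": 0.5,
  "ramp_s": 0.1,
  "seed": 42
}
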