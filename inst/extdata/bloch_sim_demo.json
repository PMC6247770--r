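{
  "pulse_train": {
    "duration_us": 600,
    "interval_us": 1200,
    "peak_b1_ut": [3, 5, 7],
    "phase_increment_deg": 0,
    "label_duration_s": 0.9
  },
  "geometry": {"thickness_mm": [1, 2, 4], "g_mean_ratio": 0.05},
  "spin": {"velocity_mm_s": [60, 124, 275], "t1_s": 2.1, "t2_s": 0.033}
}
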