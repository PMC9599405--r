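{
  "barrel_radius_mm": 4.8,
  "barrel_length_mm": 55,
  "cone_length_mm": 8,
  "needle_gauge": 20,
  "piston_speed_mm_s": 5,
  "time_step_s": 0.1,
  "wall_mode": "no_slip",
  "print_speed_mm_s": 20,
  "block_A_mm": 10,
  "block_B_mm": 20,
  "k_Pa_sn": 148.89,
  "n": 0.2025,
  "fit_range_per_s": [0.1, 10]
}
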