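{
  "group_timing": {
    "control": {"onset_mean_min": 535, "onset_between_sd": 60, "onset_within_sd": 45,
                "tst_mean_min": 455, "tst_between_sd": 50, "tst_within_sd": 45},
    "MDD":     {"onset_mean_min": 575, "onset_between_sd": 90, "onset_within_sd": 70,
                "tst_mean_min": 485, "tst_between_sd": 75, "tst_within_sd": 65},
    "BD":      {"onset_mean_min": 580, "onset_between_sd": 95, "onset_within_sd": 75,
                "tst_mean_min": 490, "tst_between_sd": 80, "tst_within_sd": 65},
    "BPD":     {"onset_mean_min": 580, "onset_between_sd": 95, "onset_within_sd": 75,
                "tst_mean_min": 480, "tst_between_sd": 80, "tst_within_sd": 65}
  },
  "device_bias": {
    "actigraph":  {"onset_min": 2,  "offset_min": 30,  "night_sd_min": 20},
    "bed":        {"onset_min": 0,  "offset_min": 0,   "night_sd_min": 20},
    "smartphone": {"onset_min": 6,  "offset_min": -38, "night_sd_min": 30}
  },
  "missing_prob": {"actigraph": 0.25, "bed": 0.20, "smartphone": 0.08, "ema": 0.10},
  "ema_misperception_sd_min": 40,
  "daylight_offset_coef_min_per_h": -6,
  "demographics": {"age_mean": 35.1, "age_sd": 12.8, "age_min": 18, "age_max": 75,
                   "prop_female": 0.739, "meq_mean": 39.2, "meq_sd": 5.2}
}
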