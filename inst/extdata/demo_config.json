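{
  "frame": {
    "fov_um": 423,
    "grid_px": 192,
    "background_au": 1.0,
    "noise_sd_au": 0.02,
    "psf_sigma_um": 1.4863,
    "seed": 1
  },
  "effect": {
    "inferior_mean_au": 1742,
    "other_mean_au": 1300,
    "inferior_sd_au": 271,
    "other_sd_au": 316,
    "diameter_range_um": [10, 50],
    "cluster_span_deg": 45,
    "n_eyes": 1
  },
  "scale_space": {},
  "variant": "welch",
  "alpha": 0.05,
  "high_threshold_um": 35,
  "seed": 1
}
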