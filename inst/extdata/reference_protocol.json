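{
  "vs": {
    "gradient_mT_m": 13,
    "duration_ms": 1.2,
    "module_ms": 50,
    "direction": [0, 0, 1],
    "direction_label": "AP",
    "enabled_in_control": false
  },
  "dual": false,
  "pld_ms": 1600,
  "bgs_ms": [50, 1160],
  "tr_ms": 3500,
  "n_pairs": 26,
  "n_prep": 3,
  "n_slices": 13,
  "slice_readout_ms": 69,
  "metadata": {
    "fov_mm": [350, 334],
    "epi_factor": 39,
    "sense_factor": 2.5
  }
}
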