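dim:
- 88
- 84
- 13
voxel_mm:
- 4.0
- 4.0
- 4.0
slice_gap_mm: 0.4
placenta_center:
- 44.5
- 42.5
- 7.0
placenta_semiaxes:
- 29.92
- 27.72
- 4.55
uterus_margin: 3.0
n_focal: 4
focal_radius: 2.2
compartments:
  focal:
    bvf: 0.85
    v_label:
    - 0.4
    - 0.4
    - 2.5
    v_readout:
    - 0.05
    - 0.05
    - 0.15
    tau_a_ms: 200.0
  maternal:
    bvf: 0.6
    v_label:
    - 0.3
    - 0.3
    - 2.0
    v_readout:
    - 0.2
    - 0.2
    - 1.0
    tau_a_ms: 350.0
  fetal:
    bvf: 0.6
    v_label:
    - 0.5
    - 0.5
    - 2.2
    v_readout:
    - 0.6
    - 0.6
    - 3.0
    tau_a_ms: 1000.0
arrival_gradient_ms: 200.0
velocity_sdlog: 0.9
target_pws_placenta: 2.4
target_pws_focal: 4.3
m0_base: 100.0
m0_septa_depth: 0.25
m0_septa_frac: 0.2
m0_smooth_amp: 0.1
t1_tissue_ms: 1820.0
t1_signal_ms: ~
arrival_ramp_ms: 0.0
noise_sd: 0.067
corrupted_pairs: []
corruption_amp: 10.0
motion_amp:
- 0
- 0
- 0
seed: 1
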