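# Small demonstration configuration: two groups of two animals, a dozen
# vessels each, on a coarser 256-px grid so the whole run stays light.
simulate:
  field_size_um: 425.10
  image_px: 256
  n_vessels: 12
  vessel_diameter_range_um: [5.0, 13.0]
  injected_mass: 25000.0
  diffusion_coeff_um2_per_min: 10.0
  ring_amplitude: 20.0
  ring_width_um: 3.0
  rise_min: 15.0
  plateau_min: 10.0
  decay_min: 15.0
  frame_interval_min: 5.0
  total_min: 40.0
  lumen_intensity: 100.0
  noise_gain: 1.0
  read_noise_sd: 2.0
  seed: 7
groups:
  control:
    n_animals: 2
    p_positive: 0.08
  treated:
    n_animals: 2
    p_positive: 0.30
volume_class: small
classify:
  mode: zscore
  z_threshold: 3.0
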