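# Example octapipe run configuration: a small degeneration cohort.
seed: 11
out_dir: octapipe-run
phantom:
  n_alines_per_bscan: 64
  n_positions: 64
  n_repeats: 5
  n_spectral: 384
  n_depth: 192
  noise_floor: 0.02
simulate:
  n_subjects: 2
  n_eyes: 2
  schedule: default
segmentation:
  widen_px: 15
  deep_shift_px: geometry
quantification:
  window_px: 20
  threshold: otsu
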