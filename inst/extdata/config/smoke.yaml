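# Minutes-scale smoke configuration: a 12-subject cohort on the smallest
# supported grid, two conditions, two training epochs. Useful to verify an
# installation end to end before launching the default matrix.
cohort:
  n_control: 6
  n_ad: 6
  dims: [16, 16, 12]
  seed: 7

conditions:
  - restore: none
  - restore: deblur
    sigma_b: 1
    crop: true

model:
  input_shape: [16, 16, 12]
  base_channels: 4
  stage_channels: [4, 8]
  epochs: 2

crop_input_shape: [16, 16, 6]

eval:
  k: 3
  seed: 1

output_dir: limbicnet_smoke
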