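# Full restoration-by-cropping experiment matrix on the benchmark cohort:
# 30 control + 30 AD phantoms on a 64 x 64 x 40 grid, degraded by a single
# scanner profile (blur sigma 2 voxels, 10 % additive noise), evaluated by
# stratified 3-fold cross-validation of the desk-scale residual CNN.
cohort:
  n_control: 30
  n_ad: 30
  dims: [64, 64, 40]
  seed: 1
  effect:
    hippocampus: 0.25
    middle_temporal: 0.25
  scanner:
    - name: bench
      blur_sigma: 2.0
      noise_sd: 0.10
      n_slices: 40

conditions:
  - restore: none
  - restore: deblur
    sigma_b: 1
  - restore: deblur
    sigma_b: 2
  - restore: denoise
    window: 3
  - restore: denoise
    window: 5
  - restore: none
    crop: true
  - restore: deblur
    sigma_b: 1
    crop: true
  - restore: deblur
    sigma_b: 2
    crop: true
  - restore: denoise
    window: 3
    crop: true
  - restore: denoise
    window: 5
    crop: true

model:
  input_shape: [32, 32, 20]
  base_channels: 16
  stage_channels: [16, 32]
  lr: 1.0e-4
  batch_size: 4
  epochs: 20
  seed: 1

crop_input_shape: [32, 32, 8]

eval:
  k: 3
  mode: cv
  seed: 1

output_dir: limbicnet_results
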