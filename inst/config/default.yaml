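# Default parameters for the adiponet pipeline.  Every stochastic stage of
# the pipeline reads its parameters from this file (possibly overridden by
# the user); seeds are supplied at call time and recorded in run manifests.

label_model:
  prevalence:            # latent metabolic classes
    diabetes: 0.25
    prediabetes: 0.25
  signal_mode: volume    # "volume" or "pattern" (matched-compartment swap)
  pattern:
    budget: 1.0          # f_visceral_upper = budget - f_visceral_lower
  depots:
    base:
      subcutaneous: 0.35
      visceral_upper: 0.30
      visceral_lower: 0.25
      thigh: 0.30
      arm: 0.25
      neck: 0.20
      breast: 0.20
    visceral_lower_by_class:
      normo: 0.20
      pre: 0.50
      diabetes: 0.80
    female_breast: 0.50
    bmi_subq_slope: 0.02   # per kg/m^2 above 25
    sd: 0.05               # depot-fraction noise SD
  insulin:                 # Matsuda-like scale
    base: 16.0
    visc_coef: 10.0        # IS drop per unit lower-visceral fraction
    thigh_coef: 2.0
    sd: 0.8
    deficit_ref: 12.0      # glycemia responds to max(deficit_ref - IS, 0)
  glycemia:
    fasting: {base: 4.9, coef: 0.60, sd: 0.25}   # mmol/l
    g2h:     {base: 5.4, coef: 1.35, sd: 0.50}   # mmol/l
    hba1c:   {base: 5.2, coef: 0.35, sd: 0.15}   # percent (NGSP)
  hba1c_conversion: {slope: 10.93, intercept: -23.5}  # pct -> mmol/mol
  followup:
    horizon: 10.0          # administrative censoring, years
    censor_mean: 4.5       # exponential censoring mean, years
    diabetes_h0: 0.010     # baseline hazard / year
    diabetes_beta: 0.9     # per HbA1c % above baseline
    microalb_h0: 0.030
    microalb_beta: 0.5
    microalb_uacr_beta: 0.3
    uacr_meanlog_ref: 8.0  # mg/g
    uacr_sdlog: 0.7

preprocess:
  trunc_sd: 3.0            # symmetric truncation band after standardization
  shift_eps: 0.01          # body minimum ends up at >= shift_eps
  voxel_stats: global      # "global" (training-fold) or "per_scan"
  antialias: false
  outlier_contamination: 0.05
  split_fractions: [0.70, 0.15, 0.15]
  strata_bins: 3           # tertiles of BMI and insulin sensitivity

augment:
  max_pad: 2               # voxels per side
  rotate: true
  rot_vertical: 10.0       # degrees
  rot_other: 5.0
  noise: true
  noise_sd: 0.05           # intensity units (body SD is ~1 after norm)
  zoom: false
  zoom_range: 0.10

crop_windows:              # vertical grid fractions
  torso: [0.12, 0.56]
  abdomen: [0.36, 0.56]

model:
  growth: 18
  init_kernel: 5
  init_filters: 8          # the alternative 4-filter setting is configurable
  dense_blocks: 3
  layers_per_block: 4
  compression: 0.5
  fc_widths: [512, 256, 128]
  dropout: 0.2
  batch_size: 8
  init_lr: 1.0e-4
  lr_decay: 0.98
  lr_cycle: 20
  max_epochs: 250
  bn_momentum: 0.9

saliency:
  sigma: 2.0               # Gaussian smoothing, voxels
  clip_quantile: 0.99      # contrast clip on |attribution|
  top_share: 0.05          # attribution voxels considered "highlighted"
  region_share: 0.10       # min share of top voxels inside a region

cluster:
  k_min: 2
  k_max: 8
  bootstrap_B: 100
  sex_stratified: true

evaluate:
  fat_threshold: 0.75      # raw-intensity fat cutoff for compartments
  pool_validation_test: true
  knn_k: 5
  rf_trees: 200

pipeline:
  tiny:  {n: 300, max_epochs: 12}
  paper: {n: 2371, max_epochs: 250}
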