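# Full default configuration of the stiptrack pipeline.
# Any subset of these keys may be given; missing keys keep their defaults.
scale_space:
  n_scales: 8          # scales S in the nonlinear scale space (>= 3)
  step: 0.15           # explicit diffusion time step (stability: <= 1/6)
  substeps: 4          # explicit steps per scale increment
  conductance_k: ~     # edge-stopping parameter; null = 90th percentile of |grad|
  conductance_form: exponential
detector:
  type: hessian_temporal   # moments | hessian_st | hessian_temporal
  kappa: 0.005             # Harris constant (moments detector)
  sigma_i: 2               # spatial integration scale (px)
  tau_i: 1                 # temporal integration scale (frames)
  min_strength_rel: 1.0e-3 # strength threshold relative to the scale-0 response
  connectivity: 8
scale_selection:
  rule: elbow_max_d2
motion:
  alpha: ~             # smoothness weight; null = (0.05 * intensity range)^2
  rho: 2               # local integration scale (px)
  n_iters: 200
  pyramid_levels: 2
segmentation:
  bandwidth_rel: 0.5   # Parzen bandwidth = bandwidth_rel * expected_radius
  min_superpixel_px: 5
  connectivity: 4
  marker_tol: 0.02     # flatness tolerance of edge-map minima extraction
detection:
  expected_radius: 6   # typical cell radius (px)
  eps_percentile: 0.15 # DBSCAN eps = this percentile of pairwise distances
  min_pts: 10
  epochs: 200
  lr: 0.01
  batch: 64
  seed: 1
refinement:
  n_iters: 50
  nu: ~                # length penalty; null = 0.2 * intensity-range^2
  window: 7            # local clustering window (px)
  solidity_threshold: 0.95
  hmax: 0.5            # h-maxima depth for distance-map splitting (px)
tracking:
  reject_threshold: 0.1    # minimum IoU for a continuation
  fallback_sigma_rel: 1
  max_daughters: 2
metrics:
  weights: {ns: 5, fn: 10, fp: 1, ed: 1, ea: 1.5, ec: 1}
# used by `stiptrack simulate`
simulate:
  shape: [128, 128]
  T: 20
  n_cells: 8
  radius_mean: 5
  radius_sd: 1
  contrast: 0.5
  background: 0.1
  noise_sd: 0.03
  noise_gain: 0.02
  motion_sd: 1.0
  elongation: 1.4
  seed: 1
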