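fpr_model:
  intercept: 6.2
  coef_t: 0.08
  coef_p: -0.01
  threshold_min: 6.6
  threshold_severe: 7.0
  threshold_extreme: 7.46
fpr_calibration:
  scale: 0.0075
  weights:
  - 1.0
  - 2.0
  - 4.0
  target_mean: 0.03
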