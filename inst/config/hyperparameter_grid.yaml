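# Hyper-parameter search space for validation-MRR model selection.
# Values are swept by run_grid(); fixed settings mirror train_config()
# defaults (dimension matched to the 768-wide text encoder output).
fixed:
  dim: 768
  batch_size: 4096
  epochs: 100
grid:
  reg_lambda: [1.0e-3, 1.0e-6, 1.0e-9, 1.0e-12, 0.0]
  align_lambda: [1.0e-3, 1.0e-6, 1.0e-9, 1.0e-12]
  lr_alpha0: [0.5, 0.25, 0.1, 0.05, 0.025, 0.01]
loss_by_scorer:
  transe: margin
  distmult: margin
  complex: logistic
  simple: logistic
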