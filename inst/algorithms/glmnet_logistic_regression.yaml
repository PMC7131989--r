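algorithm: glmnet/logistic_regression
default: {alpha: 0, lambda: 0.001}
grid:
  alpha: [0, 1]
  lambda: [0.001, 0.01, 0.1]
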