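algorithm: xgboost/xgboost
default: {nrounds: 50, max_depth: 6, eta: 0.3}
grid:
  nrounds: [20, 50]
  max_depth: [2, 6]
  eta: [0.1, 0.3]
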