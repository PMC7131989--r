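algorithm: nnet/mlp
default: {size: 3, decay: 0.1, maxit: 150}
grid:
  size: [1, 3, 5]
  decay: [0, 0.1]
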