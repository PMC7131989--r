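algorithm: e1071/naive_bayes
default: {laplace: 0}
grid:
  laplace: [0, 1]
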