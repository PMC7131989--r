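algorithm: e1071/svm_rbf
default: {cost: 1}
grid:
  cost: [0.1, 1, 10]
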