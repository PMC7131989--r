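algorithm: caret/knn
default: {k: 5}
grid:
  k: [1, 5, 11]
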