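algorithm: kernlab/svm_linear
default: {C: 1}
grid:
  C: [0.1, 1, 10]
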