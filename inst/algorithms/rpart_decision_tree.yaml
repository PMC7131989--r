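algorithm: rpart/decision_tree
default: {cp: 0.01, maxdepth: 30, minsplit: 20}
grid:
  cp: [0.001, 0.01, 0.1]
  maxdepth: [5, 30]
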