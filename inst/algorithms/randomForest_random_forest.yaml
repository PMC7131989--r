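algorithm: randomForest/random_forest
default: {ntree: 500, nodesize: 1}
grid:
  ntree: [100, 500]
  nodesize: [1, 5]
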