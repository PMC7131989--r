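algorithm: ranger/random_forest
default: {num_trees: 500, min_node_size: 1}
grid:
  num_trees: [100, 500]
  min_node_size: [1, 5]
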