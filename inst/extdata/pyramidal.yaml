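scenario: pyramidal
seed: 1
repeats: 1
output_dir: agentsim-out
pyramidal:
  n_cells: 2
  n_iterations: 120
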