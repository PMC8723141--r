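scenario: spheroid
seed: 1
repeats: 1
output_dir: agentsim-out
spheroid:
  n_cells: 2000
  n_days: 5
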