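scenario: sir
seed: 1
repeats: 3
output_dir: agentsim-out
sir:
  disease: measles
  n_iterations: 60
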