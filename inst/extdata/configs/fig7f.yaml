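# Role of ligand dimerization in cis-activation: reduced dimerization rate
scenario: sweep
sweep:
  quantity: cis_activation
  scenario: 1
  k_d: 1.0e-5
  grid: [10, 50, 200, 500, 1000, 2000, 5000, 20000]
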