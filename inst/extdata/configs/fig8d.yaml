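# Cytoplasm-confined cis-inhibition, single cell with fixed trans-ligand
scenario: sweep
ext: {L_ext: 1500}
sweep:
  quantity: compartment
  setting: fixed_trans
  localization: cytoplasmic
  grid: [0, 100, 300, 1000, 3000, 10000]
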