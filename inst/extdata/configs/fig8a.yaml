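# Oligomer-size dependence, single cell exposed to fixed trans-ligand (trimer)
scenario: sweep
ext: {L_ext: 1500}
sweep:
  quantity: oligomer
  setting: fixed_trans
  n: 3
  grid: [0, 100, 300, 1000, 3000, 10000]
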