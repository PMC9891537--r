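# Notch activity vs cis-ligand dimerization rate at high cis-ligand production (C1)
scenario: sweep
ext: {L_ext: 1500}
sweep:
  quantity: dimerization
  mode: cis
  cis: C1
  b_L: 10000
  grid: [0, 1.0e-8, 1.0e-7, 1.0e-6, 1.0e-5, 1.0e-4]
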