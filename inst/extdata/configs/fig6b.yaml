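# Notch activity vs cis-ligand production, dimer-mediated cis-inhibition (C1)
scenario: sweep
ext: {L_ext: 1500}
sweep:
  quantity: production
  mode: cis
  cis: C1
  grid: [0, 100, 300, 1000, 3000, 10000]
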