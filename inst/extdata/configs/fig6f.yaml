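# Notch activity vs trans-ligand dimerization rate at high sender production (T1)
scenario: sweep
sweep:
  quantity: dimerization
  mode: trans
  trans: T1
  b_L: 10000
  grid: [1.0e-7, 1.0e-6, 1.0e-5, 1.0e-4]
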