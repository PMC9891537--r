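# Notch activity vs trans-ligand production in the sending cell (T1)
scenario: sweep
sweep:
  quantity: production
  mode: trans
  trans: T1
  grid: [100, 300, 1000, 3000, 10000]
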