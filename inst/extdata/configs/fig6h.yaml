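# Normalized Notch activity in two identical coupled cells vs ligand production (T1)
scenario: two_cell
sweep:
  trans: T1
  grid: [50, 200, 500, 1000, 2000, 5000, 20000, 50000]
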