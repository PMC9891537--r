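# Oligomer-size dependence, two identical cells (trimer)
scenario: sweep
sweep:
  quantity: oligomer
  setting: two_cell
  n: 3
  grid: [50, 200, 1000, 5000, 20000]
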