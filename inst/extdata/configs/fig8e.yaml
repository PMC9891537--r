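# Cytoplasm-confined cis-inhibition, two identical cells
scenario: sweep
sweep:
  quantity: compartment
  setting: two_cell
  localization: cytoplasmic
  grid: [50, 200, 1000, 5000, 20000]
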