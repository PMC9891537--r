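# Cytoplasm-confined cis-inhibition, isolated cell with cis-activation
scenario: sweep
sweep:
  quantity: compartment
  setting: single_cell
  localization: cytoplasmic
  grid: [10, 50, 200, 1000, 5000, 20000]
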