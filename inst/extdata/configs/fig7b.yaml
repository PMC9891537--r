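# Cis-activation dose-response, scenario 1 (monomer cis-activation)
scenario: sweep
sweep:
  quantity: cis_activation
  scenario: 1
  grid: [10, 50, 200, 500, 1000, 2000, 5000, 20000]
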