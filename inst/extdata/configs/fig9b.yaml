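# Wing-vein patterning under an exponential Delta production gradient
scenario: lattice
lattice:
  type: wing_vein
  rows: 17
  cols: 8
  L_max: 15000
  y0: 9
  b_N: 200
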