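# Dorsoventral boundary with reduced Notch production
scenario: lattice
lattice:
  type: dv_boundary
  model: T1
  rows: 12
  cols: 6
  b_N: 350
  b_L: 200
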