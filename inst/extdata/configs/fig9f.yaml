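# Ectopic Delta stripe in the dorsal compartment
scenario: lattice
lattice:
  type: dv_boundary
  model: T1
  rows: 12
  cols: 6
  b_N: 1000
  b_L: 200
  ectopic: {species: Delta, center: 3, L_max: 15000}
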