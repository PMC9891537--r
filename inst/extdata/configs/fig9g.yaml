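# Ectopic Serrate stripe in the ventral compartment
scenario: lattice
lattice:
  type: dv_boundary
  model: T1
  rows: 12
  cols: 6
  b_N: 1000
  b_L: 200
  ectopic: {species: Serrate, center: 10, L_max: 15000}
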