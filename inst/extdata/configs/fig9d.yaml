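# Dorsoventral boundary under the ligand-dimerization model T1
scenario: lattice
lattice:
  type: dv_boundary
  model: T1
  rows: 12
  cols: 6
  b_N: 1000
  b_L: 200
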