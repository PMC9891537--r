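# Cis-inhibition relief dynamics from a dimer-loaded initial state
scenario: simulate
dynamics:
  type: cis_inhibition
  t_end: 100
  dt: 0.5
  L_ext: 1500
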