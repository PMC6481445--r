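# Scenario definitions for the published analyses: radiation delivery
# technique priced per strategy and the modelled population.
base:
  radiation_scrt: 3d
  radiation_lcrt: 3d
  population: all
scrt_imrt:
  radiation_scrt: imrt
  radiation_lcrt: 3d
  population: all
distal:
  radiation_scrt: 3d
  radiation_lcrt: 3d
  population: distal
distal_scrt_imrt:
  radiation_scrt: imrt
  radiation_lcrt: 3d
  population: distal
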