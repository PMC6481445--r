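p_local_recurrence_10y: 0.071
p_local_recurrence_10y_scrt: .na.real
p_distant_recurrence_10y: 0.3
p_death_metastatic_5y: 0.86
p_apr_lcrt: 0.17
p_lar_lcrt: 0.83
p_apr_scrt: 0.28
p_lar_scrt: 0.72
p_salvage_lr: 0.25
u_ned_apr: 0.5
u_ned_lar: 0.59
u_local_recurrence: 0.4
u_salvaged_lr: 0.4
u_distant_recurrence: 0.2
u_death: 0.0
c_apr: 21569.0
c_lar: 35569.0
c_capecitabine_cycle: 1890.0
c_colostomy_supplies: 3427.0
c_lcrt_3d: 19311.0
c_lcrt_imrt: 25502.0
c_scrt_3d: 7223.0
c_scrt_imrt: 7814.0
c_salvage: 21569.0
discount_rate: 0.03
wtp: 100000.0
horizon_cycles: 10
cycle_length_years: 1.0
start_age: 65
n_adjuvant_chemo_cycles: 0.0
distal_lar_conversion_lcrt: 0.39
distal_lar_conversion_scrt: 0.19
radiation_scrt: 3d
radiation_lcrt: 3d
population: all
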