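## shared fixtures built in code

# near-zero background mortality (the constructor requires q > 0)
zero_mortality <- function() make_life_table(q_ref = 1e-12, growth = 0)

# event-free cohort: no recurrence, no cancer death, perfect NED utility
params_no_events <- function() {
  p <- rc_parameters()
  p <- set_parameter(p, "p_local_recurrence_10y", 0)
  p <- set_parameter(p, "p_distant_recurrence_10y", 0)
  p <- set_parameter(p, "p_death_metastatic_5y", 0)
  p <- set_parameter(p, "u_ned_lar", 1)
  p <- set_parameter(p, "u_ned_apr", 1)
  p
}

base_lt <- default_life_table()
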