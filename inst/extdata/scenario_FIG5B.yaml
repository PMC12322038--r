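schema_version: 1.0
name: FIG5B
genome:
  length: 4033000.0
  parS_deg: -59.0
  parS_weight: 1.0
protocol:
  initial_temp: 42.0
  events:
  - time: 0.0
    kind: SET_TEMP
    value: 30.0
  - time: 15.0
    kind: SET_TEMP
    value: 42.0
  - time: 23.621212121212121
    kind: ADD_IPTG
    value: .na.real
  - time: 23.621212121212121
    kind: ADD_HPURA
    value: .na.real
  - time: 38.621212121212125
    kind: SAMPLE
    value: .na.real
  - time: 48.621212121212125
    kind: SAMPLE
    value: .na.real
rep_params:
  f_pre: 0.18
  t_init_mean: 5.0
  v30: 40.0
  v42: 66.0
  p_stall: 0.004
smc_params:
  n_smc: 40
  v_to_ter: 71.5
  v_to_ori: 49.0
  tau_dissoc: 1200.0
  parS_weight: 1.0
  background_weight: 2.5e-08
  tau_unload: 30.0
  tau_bypass: 120.0
  engagement_model: combined
  t_memory: 700.0
  load_rate: 0.016666666666667
  loading_lag: 5.0
  bypass_offset: 1000.0
sample_times:
- 38.621212121212125
- 48.621212121212125
constitutive_loading: no
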