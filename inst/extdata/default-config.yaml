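params:
  trunk_height: 0.92
  m_trunk: 48.0
  m_foot: 12.0
  g: 9.8
  k_leg_flight: 6000.0
  k_leg_contact: 16000.0
  b_leg: 350.0
  ext_mult: 10.0
  ext_ratio: 1.1
  k_inter: 10000.0
  b_inter: 2000.0
  k_ground: 30000.0
  b_ground: 2500.0
  b_friction: 20000.0
  k_aux: 6000.0
  b_aux: 300.0
  d_aux: 0.15
  d_balance: 0.2
  swing_ratio: 0.6
  gain: 3000.0
  eps1: 1.0e-10
  eps2: 0.0001
  dt: 1.0e-05
  fall_z: 0.4
protocol:
  target_speed: 2.0
  t_start: 1.5
  spacing: 0.03
  n_trials: 101.0
  reach_dist: 2.0
  timeout: 15.0
output:
  out_dir: '.'
  log_dt: 0.001
  format: csv
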