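# Ex vivo bovine liver, single Cu-wire heat source, setpoint 45 degC.
name: liver_single_45
duration_s: 900
seed: 7
substep_s: 0.1
controller:
  kp: 0.2
  ki: 1.0e-5
  kd: 2.5
  setpoint_C: 45
  sample_interval_s: 1
  u_min_V: 0
  u_max_V: 1.25
  derivative_filter_tau_s: 2
  input_filter_tau_s: 3
actuator:
  v_zero_V: 0
  v_full_V: 1.25
  H_full_kA_per_m: 9.8
  frequency_kHz: 160
  H_cap_kA_per_m: 9.8
source:
  type: cu
  SAR_Cu_W_per_g: 25
  mass_g: 0.104
  H_ref_kA_per_m: 9.8
plant:
  type: lumped
  K_gain_C_per_W_m3: 2.92e-3
  tau_p_s: 109000
  dead_time_s: 1
  T0_C: 23
  coupling_per_s: 1.0e-5
  core_tau_s: 600
  T_core0_C: 23
sensors:
  names: [MHT, periphery]
  map: {MHT: target, periphery: core}
  control: MHT
  lag_tau_s: 0.05
  noise_sd_C: 0.02
  bias_C: 0
  resolution_C: 0.1
safety:
  thresholds_C: {MHT: 50, periphery: 40}
  deadband_C: 0
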