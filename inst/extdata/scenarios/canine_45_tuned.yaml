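# In vivo canine brain, MNP heat source, tuned gains, setpoint 45 degC.
# Plant calibrated so the closed loop reaches the setpoint in ~120 s.
name: canine_45_tuned
duration_s: 900
seed: 7
substep_s: 0.1
controller:
  kp: 2
  ki: 1.0e-4
  kd: 2.5
  setpoint_C: 45
  sample_interval_s: 1
  u_min_V: 0
  u_max_V: 5
  derivative_filter_tau_s: 2
  input_filter_tau_s: 3
actuator:
  v_zero_V: 0
  v_full_V: 1.25
  H_full_kA_per_m: 9.8
  frequency_kHz: 160
  H_cap_kA_per_m: 10
source:
  type: mnp
  SLP_ref_W_per_g: 100
  H_ref_kA_per_m: 9.8
  cFe_mg_per_mL: 80
  sigma_s_mm: 3
plant:
  type: lumped
  K_gain_C_per_W_m3: 2.44e-4
  tau_p_s: 22900
  dead_time_s: 2
  T0_C: 37
  coupling_per_s: 2.0e-5
  core_tau_s: 600
  T_core0_C: 38.5
sensors:
  names: [MHT, subcutaneous, rectal]
  map: {MHT: target, subcutaneous: core, rectal: core}
  control: MHT
  lag_tau_s: 0.05
  noise_sd_C: 0.02
  bias_C: 0
  resolution_C: 0.1
safety:
  thresholds_C: {MHT: 50, subcutaneous: 45, rectal: 40}
  deadband_C: 0
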