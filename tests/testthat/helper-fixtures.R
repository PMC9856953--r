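# shared fixture builders; everything is generated in code at test time

const_trace <- function(temp, minutes, step = 1, label = "MHT") {
  n <- as.integer(minutes * 60 / step)
  temperature_trace(seq(0, by = step, length.out = n), rep(temp, n), label)
}

# small, fast closed-loop test scenario on a lumped plant
test_scenario <- function(setpoint = 44, T0 = 37, duration = 300,
                          gains = pid_gains(0.5, 0.01, 2),
                          K_gain = 2e-5, tau_p = 40, dead_time = 2,
                          noise_sd = 0, resolution = 1e-6,
                          H_cap = 9800, thresholds = c(MHT = 50),
                          seed = 11L) {
  src <- mnp_source(SLP_ref = 6.25, H_ref = 9800, cFe = 8e4)  # P_full 5e5 W/m3
  scenario(
    name = "test", duration = duration,
    controller = controller_config(gains, setpoint = setpoint,
                                   u_min = 0, u_max = 1.25),
    actuator = actuator_map(v_full = 1.25, H_full = 9800,
                            frequency = 160e3, H_cap = H_cap),
    source = src,
    plant = lumped_plant_config(K_gain = K_gain, tau_p = tau_p,
                                dead_time = dead_time, T0 = T0),
    sensors = sensor_config(c("MHT", "safety"), lag_tau = 0.05,
                            noise_sd = noise_sd, bias = 0,
                            resolution = resolution),
    sensor_map = c(MHT = "target", safety = "core"),
    safety = safety_config(thresholds),
    control_sensor = "MHT", seed = seed)
}
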