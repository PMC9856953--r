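test_that("a zero-gain controller keeps the field off and the plant at baseline", {
  scn <- test_scenario(gains = pid_gains(0, 0, 0), duration = 60)
  log <- run_closed_loop(scn)
  expect_true(all(log$H_A_per_m == 0))
  expect_true(all(abs(log$T_true_ctrl - 37) < 1e-9))
})

test_that("a short closed-loop run equals a hand-wired composition of the modules", {
  scn <- test_scenario(duration = 20, noise_sd = 0, resolution = 0.1)
  log <- run_closed_loop(scn)

  # manual loop in the documented order:
  # sense -> gate -> control -> actuate -> integrate
  pstate <- plant_init(scn$plant)
  sstate <- sensor_init(scn$sensors, c(37, 37))
  cstate <- pid_reset(scn$controller)
  gate <- gate_init()
  H_seq <- numeric(20); read_seq <- numeric(20)
  for (k in 1:20) {
    analog <- sstate$lagged + sstate$bias
    display <- sign(analog) * floor(abs(analog) / 0.1 + 0.5) * 0.1
    names(display) <- scn$sensors$names
    gate <- supervise(display, scn$safety, gate)
    out <- pid_step(cstate, analog[[1L]], scn$controller)
    cstate <- out$state
    H <- voltage_to_field(out$u, scn$actuator)
    if (!gate$power_allowed) H <- 0
    P <- source_power(scn$source, H)
    for (i in 1:10) {
      pstate <- step_lumped(pstate, P, 0.1, scn$plant)
      truths <- c(pstate$temps[["target"]], pstate$temps[["core"]])
      sstate <- sensor_advance(sstate, truths, 0.1, scn$sensors)
    }
    H_seq[k] <- H
    read_seq[k] <- display[[1L]]
  }
  expect_equal(log$H_A_per_m, H_seq, tolerance = 1e-12)
  expect_equal(log$T_MHT, read_seq, tolerance = 1e-12)
})

test_that("identical scenario and seed give bit-identical session logs", {
  scn <- test_scenario(duration = 120, noise_sd = 0.05, resolution = 0.1)
  a <- run_closed_loop(scn, seed = 13)
  b <- run_closed_loop(scn, seed = 13)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- run_closed_loop(scn, seed = 14)
  expect_false(identical(a$T_MHT, c2$T_MHT))
})

test_that("integral action drives the steady-state error below 1% on a lumped plant", {
  scn <- test_scenario(duration = 600, noise_sd = 0.02, resolution = 0.1)
  rep <- performance_report(run_closed_loop(scn), scn)
  expect_true(rep$settled)
  expect_lt(rep$ss_error_pct, 1)
})

test_that("pulse sequences scale initial heating quadratically with the field", {
  scn <- test_scenario(noise_sd = 0, resolution = 1e-9)
  one <- run_pulse_sequence(scn,
    data.frame(H_A_per_m = 2000, duration_s = 30, cooldown_s = 30))
  two <- run_pulse_sequence(scn,
    data.frame(H_A_per_m = 4000, duration_s = 30, cooldown_s = 30))
  lead <- 10  # lead-in samples before the pulse
  slope1 <- one$T_true_ctrl[lead + 5] - one$T_true_ctrl[lead + 4]
  slope2 <- two$T_true_ctrl[lead + 5] - two$T_true_ctrl[lead + 4]
  expect_equal(slope2 / slope1, 4, tolerance = 1e-6)

  # zero-amplitude pulse: flat log; cap violation: error
  flat <- run_pulse_sequence(scn,
    data.frame(H_A_per_m = 0, duration_s = 30, cooldown_s = 10))
  expect_true(all(abs(flat$T_true_ctrl - 37) < 1e-9))
  expect_error(run_pulse_sequence(scn,
    data.frame(H_A_per_m = 2e4, duration_s = 10)), "cap")

  # structure: one pulse produces a rise and a decay episode
  tr <- two$T_true_ctrl
  expect_gt(max(tr), 37.5)
  expect_lt(tr[length(tr)], max(tr))
})

test_that("safety supremacy holds across randomised gains and the gate resumes", {
  # low threshold forces trips; randomised aggressive gains
  set.seed(77)
  for (i in 1:5) {
    scn <- test_scenario(setpoint = 44, thresholds = c(MHT = 42),
                         gains = pid_gains(runif(1, 0.5, 5),
                                           runif(1, 0, 0.05),
                                           runif(1, 0, 3)),
                         duration = 240, noise_sd = 0.02, resolution = 0.1,
                         seed = 100L + i)
    log <- run_closed_loop(scn)
    denied <- grepl("^TRIP", log$gate)
    expect_gt(sum(denied), 0)                  # the supervisor did trip
    expect_true(all(log$H_A_per_m[denied] == 0))
    # the step after any denied verdict never commands field while denied
    after <- which(denied[-nrow(log)]) + 1L
    still_denied <- grepl("^TRIP", log$gate[after])
    expect_true(all(log$H_A_per_m[after][still_denied] == 0))
    expect_gt(sum(!denied[min(which(denied)):nrow(log)]), 0)  # resumed
  }
})

test_that("gain grid search ranks a well-tuned triple above an oscillatory one", {
  scn <- test_scenario(duration = 240, K_gain = 2e-4, tau_p = 100,
                       noise_sd = 0, resolution = 1e-6)
  grid <- data.frame(Kp = c(0.5, 8), Ki = c(0.01, 0.3), Kd = c(2, 0))
  res <- tune_gains_grid(scn, grid)
  expect_equal(res$table$Kp[1], 0.5)
  expect_true(res$table$pass[1])
  expect_equal(res$best$Kp, 0.5)

  # grid of one returns that triple with its report
  one <- tune_gains_grid(scn, data.frame(Kp = 0.5, Ki = 0.01, Kd = 2))
  expect_equal(nrow(one$table), 1L)
  expect_equal(one$best$Kd, 2)

  # impossible criteria: empty passing set, diagnostics retained
  none <- tune_gains_grid(scn, grid,
                          criteria = c(rise_s = 0.1, overshoot_pct = 5,
                                       settling_s = 300, ss_error_pct = 1))
  expect_null(none$best)
  expect_false(any(none$table$pass))
})

test_that("model-based retuning closes the loop within the design criteria", {
  scn <- test_scenario(duration = 300, noise_sd = 0, resolution = 1e-9)
  pulses <- data.frame(H_A_per_m = c(4000, 8000), duration_s = c(30, 30),
                       cooldown_s = c(90, 150))
  plog <- run_pulse_sequence(scn, pulses)
  gains <- retune_from_pulses(scn, plog)

  scn_t <- scn
  scn_t$controller$gains <- gains
  rep <- performance_report(run_closed_loop(scn_t), scn_t)
  expect_true(rep$rise_reached); expect_lt(rep$t_r, 60)
  expect_lt(rep$M_p, 5)
  expect_true(rep$settled); expect_lt(rep$t_ss, 300)
  expect_lt(rep$ss_error_pct, 1)

  # a slower plant never gets a smaller proportional gain (IMC monotonicity)
  scn2 <- test_scenario(tau_p = 80, noise_sd = 0, resolution = 1e-9)
  plog2 <- run_pulse_sequence(scn2, pulses)
  gains2 <- retune_from_pulses(scn2, plog2)
  expect_gte(gains2$Kp, gains$Kp)

  flat <- plog
  flat$H_A_per_m[] <- 0
  expect_error(retune_from_pulses(scn, flat), "no pulse")
})

test_that("the engine drives a radial plant scenario end to end", {
  src <- mnp_source(SLP_ref = 6.25, H_ref = 9800, cFe = 8e4)
  plant <- radial_plant_config("sphere", R_max = 0.03, n_cells = 60,
                               k = 0.5, rho = 1050, c_p = 3600,
                               omega_b = 0.004, T_a = 37,
                               boundary = list(type = "fixed_T", T_b = 37))
  plant$source_field <- gaussian_source_profile(plant, 4e6, 3e-3)
  scn <- scenario(
    name = "radial-test", duration = 180,
    controller = controller_config(pid_gains(0.5, 0.02, 2), setpoint = 42,
                                   u_min = 0, u_max = 1.25),
    actuator = actuator_map(v_full = 1.25, H_full = 9800, frequency = 160e3),
    source = src, plant = plant,
    sensors = sensor_config(c("MHT", "margin"), noise_sd = 0, bias = 0,
                            resolution = 1e-6),
    sensor_map = c(MHT = 0.0015, margin = 0.02),
    safety = safety_config(c(MHT = 50, margin = 40)),
    control_sensor = "MHT", seed = 5L)
  log <- run_closed_loop(scn)
  expect_equal(nrow(log), 180L)
  # the controlled point approaches the setpoint; the margin stays cooler
  expect_lt(abs(log$T_MHT[180] - 42), 0.5)
  expect_lt(log$T_margin[180], 40)
})
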