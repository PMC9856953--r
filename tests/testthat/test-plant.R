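test_that("lumped plant stays at equilibrium and follows the first-order closed form", {
  cfg <- lumped_plant_config(K_gain = 2e-5, tau_p = 40, T0 = 23)
  st <- plant_init(cfg)
  for (i in 1:10) st <- step_lumped(st, 0, 1, cfg)
  expect_equal(temperature_at(st, cfg, "target"), 23)

  # constant drive: T(t) = T0 + K P (1 - exp(-t/tau)), checked at t = tau
  P <- 2e5
  st <- plant_init(cfg)
  for (i in 1:40) st <- step_lumped(st, P, 1, cfg)
  want <- 23 + 2e-5 * P * (1 - exp(-1))
  expect_equal(temperature_at(st, cfg, "target"), want, tolerance = 1e-9)
})

test_that("dead time shifts the response without reshaping it", {
  base <- lumped_plant_config(K_gain = 2e-5, tau_p = 40, T0 = 23)
  lag3 <- lumped_plant_config(K_gain = 2e-5, tau_p = 40, dead_time = 3, T0 = 23)
  run <- function(cfg, n) {
    st <- plant_init(cfg)
    sapply(seq_len(n), function(i) {
      st <<- step_lumped(st, 2e5, 1, cfg)
      temperature_at(st, cfg, "target")
    })
  }
  a <- run(base, 30)
  b <- run(lag3, 33)
  expect_equal(b[4:33], a[1:30], tolerance = 1e-12)
  expect_equal(b[1:3], rep(23, 3))
})

test_that("coupled core node exchanges heat both ways", {
  cfg <- lumped_plant_config(K_gain = 1e-5, tau_p = 60, T0 = 37,
                             coupling = 0.01, core_tau = 300, T_core0 = 37)
  st <- plant_init(cfg)
  for (i in 1:300) st <- step_lumped(st, 5e5, 1, cfg)
  expect_gt(temperature_at(st, cfg, "core"), 37)        # core warms
  Tt <- temperature_at(st, cfg, "target")
  # target is pulled below its uncoupled asymptote by the cooler core
  expect_lt(Tt, 37 + 1e-5 * 5e5)
})

test_that("radial steady state matches the analytic conduction profile in a sphere", {
  n <- 200
  Q <- 5e4; k <- 0.5; Tb <- 37; R <- 0.02
  cfg <- radial_plant_config("sphere", R_max = R, n_cells = n, k = k,
                             rho = 1050, c_p = 3600, omega_b = 0, T_a = Tb,
                             boundary = list(type = "fixed_T", T_b = Tb),
                             source_field = Q)
  st <- plant_init(cfg)
  st <- step_radial(st, 1, Inf, cfg)  # direct steady solve
  r <- (seq_len(n) - 0.5) * (R / n)
  analytic <- Tb + Q * (R^2 - r^2) / (6 * k)
  expect_lt(max(abs(st$temps - analytic) / (analytic - Tb + 1e-12)), 0.01)
  # centre value via interpolation within 1%
  expect_equal(temperature_at(st, cfg, 0), Tb + Q * R^2 / (6 * k),
               tolerance = 0.01)
})

test_that("perfusion-dominated limit gives the algebraic temperature rise", {
  cfg <- radial_plant_config("sphere", R_max = 0.05, n_cells = 64,
                             k = 1e-4, rho = 1050, c_p = 3600,
                             omega_b = 0.05, rho_b_c_b = 3.8e6, T_a = 37,
                             boundary = list(type = "fixed_T", T_b = 37),
                             source_field = 1e5)
  st <- plant_init(cfg)
  st <- step_radial(st, 1, Inf, cfg)
  # interior: rho_b c_b omega_b (T - T_a) = Q
  want <- 1e5 / (3.8e6 * 0.05)
  interior <- st$temps[5:50]
  expect_equal(interior, rep(37 + want, length(interior)), tolerance = 1e-3)
})

test_that("radial field respects equilibrium, maximum principle and grid refinement", {
  mk <- function(n) {
    cfg <- radial_plant_config("sphere", R_max = 0.03, n_cells = n, k = 0.5,
                               rho = 1050, c_p = 3600, omega_b = 0, T_a = 23,
                               boundary = list(type = "fixed_T", T_b = 23))
    cfg$source_field <- gaussian_source_profile(cfg, 4e5, 3e-3)
    cfg
  }
  # equilibrium: no sources, uniform field stays put
  cfg0 <- mk(64); cfg0$source_field[] <- 0
  st <- plant_init(cfg0)
  for (i in 1:5) st <- step_radial(st, 0, 1, cfg0)
  expect_equal(st$temps, rep(23, 64), tolerance = 1e-12)

  # maximum principle: non-negative sources never cool below baseline
  cfg1 <- mk(128)
  st <- plant_init(cfg1)
  for (i in 1:120) st <- step_radial(st, 1, 1, cfg1)
  expect_true(all(st$temps >= 23 - 1e-9))
  expect_true(all(diff(st$temps) <= 1e-9))  # hottest at the centre

  # refinement: sensor-position temperature changes < 0.5% on grid doubling
  probe_T <- function(n, t_end = 120) {
    cfg <- mk(n)
    st <- plant_init(cfg)
    for (i in seq_len(t_end)) st <- step_radial(st, 1, 1, cfg)
    temperature_at(st, cfg, 1.5e-3)
  }
  T1 <- probe_T(100); T2 <- probe_T(200)
  expect_lt(abs(T2 - T1) / (T1 - 23), 0.005)
})

test_that("radial stepper is stable at coarse steps (no node oscillation)", {
  cfg <- radial_plant_config("cylinder", R_max = 0.05, n_cells = 400,
                             k = 0.5, rho = 1050, c_p = 3600,
                             omega_b = 0.004, T_a = 37,
                             boundary = list(type = "fixed_T", T_b = 37))
  cfg$source_field <- gaussian_source_profile(cfg, 8e5, 3e-3)
  st <- plant_init(cfg)
  for (i in 1:60) st <- step_radial(st, 1, 1, cfg)
  d <- diff(st$temps)
  # smooth decay away from the centre: no oscillation above numerical noise
  d <- d[abs(d) > 1e-6]
  expect_lte(sum(diff(sign(d)) != 0), 1)
})

test_that("temperature interpolation is linear between cell centres", {
  cfg <- radial_plant_config("sphere", R_max = 0.01, n_cells = 10, k = 0.5,
                             rho = 1000, c_p = 4000, T_a = 30)
  st <- plant_init(cfg)
  st$temps <- seq(40, 31, length.out = 10)
  ctr <- (seq_len(10) - 0.5) * 1e-3
  expect_equal(temperature_at(st, cfg, ctr[3]), st$temps[3])
  expect_equal(temperature_at(st, cfg, mean(ctr[3:4])),
               mean(st$temps[3:4]))
  mid <- temperature_at(st, cfg, ctr[5] + 0.3e-3)
  expect_true(mid <= st$temps[5] && mid >= st$temps[6])
  expect_error(temperature_at(st, cfg, 0.02), "outside")
})

test_that("pulse-response identification recovers known plant parameters", {
  scn <- test_scenario(K_gain = 2e-5, tau_p = 40, dead_time = 2,
                       noise_sd = 0, resolution = 1e-9)
  pulses <- data.frame(H_A_per_m = c(4000, 8000), duration_s = c(30, 30),
                       cooldown_s = c(90, 150))
  log <- run_pulse_sequence(scn, pulses)
  fit <- identify_fopdt(log, scn$source, sensor = "T_MHT")
  expect_equal(fit$K_gain, 2e-5, tolerance = 0.01)
  expect_equal(fit$tau_p, 40, tolerance = 0.01)
  expect_equal(fit$dead_time, 2, tolerance = 0.05)

  # with seeded sensor noise, recovery within 5%
  scn_n <- test_scenario(K_gain = 2e-5, tau_p = 40, dead_time = 2,
                         noise_sd = 0.1, resolution = 0.1, seed = 21L)
  log_n <- run_pulse_sequence(scn_n, pulses)
  fit_n <- identify_fopdt(log_n, scn_n$source, sensor = "T_MHT")
  expect_equal(fit_n$K_gain, 2e-5, tolerance = 0.05)
  expect_equal(fit_n$tau_p, 40, tolerance = 0.05)

  # a flat log carries no identifiable pulse
  flat <- log
  flat$H_A_per_m[] <- 0
  expect_error(identify_fopdt(flat, scn$source), "no pulse")
})
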