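first_order <- function(T0, T_ref, tau, n = 600, step = 1) {
  t <- seq(0, by = step, length.out = n)
  temperature_trace(t, T0 + (T_ref - T0) * (1 - exp(-t / tau)))
}

second_order <- function(T0, T_ref, zeta, wn, n = 2000, step = 0.05) {
  t <- seq(0, by = step, length.out = n)
  wd <- wn * sqrt(1 - zeta^2)
  y <- 1 - exp(-zeta * wn * t) *
    (cos(wd * t) + zeta / sqrt(1 - zeta^2) * sin(wd * t))
  temperature_trace(t, T0 + (T_ref - T0) * y)
}

test_that("rise time inverts the first-order closed form and flags unreachable traces", {
  tr <- first_order(23, 25, tau = 30)
  # 90% of the step is reached at tau*ln(10)
  expect_equal(as.numeric(rise_time(tr, 25, 23)), 30 * log(10), tolerance = 1 / (30 * log(10)))

  # instant jump at the first sample after onset
  jump <- temperature_trace(0:59, c(23, rep(25, 59)))
  expect_lte(as.numeric(rise_time(jump, 25, 23)), 1)

  never <- temperature_trace(0:59, rep(23.5, 60))
  expect_true(is.na(rise_time(never, 25, 23)))
  expect_false(attr(rise_time(never, 25, 23), "reached"))
  expect_error(rise_time(tr, 22, 23), "exceed")
})

test_that("settling time is the last excursion outside the band", {
  t <- seq(0, 120, by = 0.1)
  y <- 45 + 2 * exp(-t / 15) * cos(2 * pi * t / 12)
  tr <- temperature_trace(t, y)
  last_out <- max(t[abs(y - 45) > 0.5])
  expect_equal(as.numeric(settling_time(tr, 45)), last_out)

  inside <- temperature_trace(0:99, rep(45.2, 100))
  expect_equal(as.numeric(settling_time(inside, 45)), 0)

  diverging <- temperature_trace(0:99, 45 + 0.02 * (0:99))
  expect_true(is.na(settling_time(diverging, 45)))

  # a trace engineered to exit the band for the last time at 39.7 s
  t2 <- seq(0, 200, by = 0.1)
  y2 <- ifelse(t2 <= 39.7, 45.8, 45.2)
  expect_equal(as.numeric(settling_time(temperature_trace(t2, y2), 45)), 39.7)
})

test_that("overshoot matches the classical second-order closed form", {
  for (zeta in c(0.3, 0.5, 0.7)) {
    tr <- second_order(37, 45, zeta, wn = 1)
    want <- 100 * exp(-pi * zeta / sqrt(1 - zeta^2))
    expect_equal(overshoot_pct(tr, 45, 37), want, tolerance = 0.01)
  }
  # zeta = 0.5 is the textbook 16.3%
  expect_equal(overshoot_pct(second_order(37, 45, 0.5, 1), 45, 37),
               16.3, tolerance = 0.01)

  capped <- first_order(23, 25, 30)
  expect_equal(overshoot_pct(capped, 25, 23), 0)

  # peak exactly 5% of the step above the setpoint
  peaky <- temperature_trace(0:99, c(seq(23, 25.1, length.out = 50),
                                     rep(25, 50)))
  expect_equal(overshoot_pct(peaky, 25, 23), 5)
})

test_that("steady-state error reports mean absolute deviation over the late window", {
  flat <- temperature_trace(0:999, c(seq(40, 45, length.out = 200),
                                     rep(45, 800)))
  sse <- steady_state_error(flat, 45)
  expect_equal(sse$abs_degC, 0)

  offset <- temperature_trace(0:999, c(seq(40, 44.9, length.out = 200),
                                       rep(44.9, 800)))
  sse2 <- steady_state_error(offset, 45)
  expect_equal(sse2$abs_degC, 0.1)
  expect_equal(sse2$pct, 0.1 / 45 * 100)

  # symmetric square ripple: mean |error| is the ripple amplitude
  ripple <- temperature_trace(0:999, 45 + 0.1 * rep(c(1, -1), 500))
  expect_equal(steady_state_error(ripple, 45, band = 0.5)$abs_degC, 0.1)

  unsettled <- temperature_trace(0:99, 45 + 0.02 * (0:99))
  expect_false(steady_state_error(unsettled, 45)$settled)
})

test_that("metrics are invariant to a uniform time shift and ordered t_r <= t_ss", {
  tr <- second_order(37, 45, 0.4, 0.2, n = 4000, step = 0.25)
  shifted <- temperature_trace(tr$times + 500, tr$temps)
  expect_equal(as.numeric(rise_time(shifted, 45, 37)),
               as.numeric(rise_time(tr, 45, 37)))
  expect_equal(as.numeric(settling_time(shifted, 45)),
               as.numeric(settling_time(tr, 45)))
  expect_equal(overshoot_pct(shifted, 45, 37), overshoot_pct(tr, 45, 37))
  expect_lte(as.numeric(rise_time(tr, 45, 37)),
             as.numeric(settling_time(tr, 45)))
})

test_that("session report equals independently recomputed metrics", {
  scn <- test_scenario(duration = 240)
  log <- run_closed_loop(scn)
  rep <- performance_report(log, scn)

  tr <- trace_from_log(log, "MHT")
  expect_equal(rep$t_r, as.numeric(rise_time(tr, 44, log$T_MHT[1])))
  expect_equal(rep$t_ss, as.numeric(settling_time(tr, 44)))
  expect_equal(rep$M_p, overshoot_pct(tr, 44, log$T_MHT[1]))
  expect_equal(rep$cem43, cem43(tr))
  expect_named(rep$criteria_pass,
               c("rise_lt_60s", "overshoot_lt_5pct", "settling_lt_5min",
                 "ss_error_lt_1pct", "cem43_in_window"))

  # a trace peaking 6% above the step fails the overshoot criterion
  fake <- log
  peak_row <- 120
  fake$T_MHT[peak_row] <- 44 + 0.06 * (44 - fake$T_MHT[1])
  rep2 <- performance_report(fake, scn)
  expect_false(rep2$criteria_pass[["overshoot_lt_5pct"]])

  expect_error(performance_report(data.frame(t_s = 0:5), scn), "incomplete")
})
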