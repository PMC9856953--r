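#' Simulation scenario
#'
#' Bundles every component of a controller-in-the-loop session: plant,
#' heat source, actuator calibration, sensor probe, safety supervisor and
#' PID configuration, plus the mapping from sensors to plant locations.
#'
#' @param name Scenario name.
#' @param duration Session duration, s.
#' @param controller A [controller_config()].
#' @param actuator An [actuator_map()].
#' @param source A heat source ([mnp_source()], [cu_source()] or
#'   [eddy_params()]).
#' @param plant A [lumped_plant_config()] or [radial_plant_config()]. For
#'   radial plants, `plant$source_field` must be the power-density profile
#'   at the source's reference field; the engine scales it with the
#'   commanded field.
#' @param sensors A [sensor_config()].
#' @param sensor_map Named vector mapping each sensor to a plant location:
#'   node names (`"target"`/`"core"`) for lumped plants, radii in m for
#'   radial plants.
#' @param safety A [safety_config()].
#' @param control_sensor Id of the sensor driving the controller.
#' @param seed Default RNG seed for the session (integer).
#' @param substep Plant integration substep within each control interval,
#'   s (default 0.1).
#' @return An object of class `scenario`.
#' @export
scenario <- function(name, duration, controller, actuator, source, plant,
                     sensors, sensor_map, safety, control_sensor,
                     seed = 7L, substep = 0.1) {
  stopifnot(inherits(controller, "controller_config"),
            inherits(actuator, "actuator_map"),
            inherits(source, "heat_source"),
            inherits(plant, "plant_config"),
            inherits(sensors, "sensor_config"),
            inherits(safety, "safety_config"),
            duration > 0, substep > 0)
  if (!control_sensor %in% sensors$names) {
    stop("scenario: control_sensor '", control_sensor,
         "' is not a configured sensor", call. = FALSE)
  }
  if (is.null(names(sensor_map)) ||
      !all(sensors$names %in% names(sensor_map))) {
    stop("scenario: sensor_map must name a location for every sensor",
         call. = FALSE)
  }
  if (!all(names(safety$thresholds) %in% sensors$names)) {
    stop("scenario: safety thresholds reference unknown sensors",
         call. = FALSE)
  }
  structure(list(name = name, duration = duration, controller = controller,
                 actuator = actuator, source = source, plant = plant,
                 sensors = sensors, sensor_map = sensor_map,
                 safety = safety, control_sensor = control_sensor,
                 seed = as.integer(seed), substep = substep),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  g <- x$controller$gains
  cat(sprintf("<scenario '%s': %g s, T_ref %g degC, gains (%g, %g, %g), %s plant>\n",
              x$name, x$duration, x$controller$setpoint, g$Kp, g$Ki, g$Kd,
              if (inherits(x$plant, "lumped_plant_config")) "lumped" else "radial"))
  invisible(x)
}

# true temperatures at the sensor locations
sensor_truth <- function(scn, pstate) {
  locs <- scn$sensor_map[scn$sensors$names]
  if (inherits(scn$plant, "lumped_plant_config")) {
    as.numeric(pstate$temps[as.character(locs)])
  } else {
    vapply(as.numeric(locs), function(r)
      temperature_at(pstate, scn$plant, r), numeric(1L))
  }
}

advance_plant <- function(scn, pstate, sstate, P, drive, dt_ctrl) {
  n_sub <- max(1L, as.integer(round(dt_ctrl / scn$substep)))
  dt <- dt_ctrl / n_sub
  lumped <- inherits(scn$plant, "lumped_plant_config")
  for (i in seq_len(n_sub)) {
    pstate <- if (lumped) step_lumped(pstate, P, dt, scn$plant)
              else step_radial(pstate, drive, dt, scn$plant)
    sstate <- sensor_advance(sstate, sensor_truth(scn, pstate), dt,
                             scn$sensors)
  }
  list(pstate = pstate, sstate = sstate)
}

# shared sense -> gate -> command -> actuate -> integrate loop.
# u_fun(k, readings, cstate) returns list(u=..., cstate=...) for closed
# loop; for open-loop sequences H_cmd[k] overrides the actuator input.
run_session <- function(scn, seed, n_steps, u_fun = NULL, H_cmd = NULL) {
  set.seed(seed)
  dt_ctrl <- scn$controller$sample_interval
  dp <- dose_params()
  lumped <- inherits(scn$plant, "lumped_plant_config")
  f <- scn$actuator$frequency
  P_ref <- source_power(scn$source, ref_field(scn$source), f)

  pstate <- plant_init(scn$plant)
  truth0 <- sensor_truth(scn, pstate)
  sstate <- sensor_init(scn$sensors, truth0)
  cstate <- pid_reset(scn$controller)
  gate <- gate_init()

  ns <- scn$sensors$names
  n_sens <- length(ns)
  M_read <- matrix(NA_real_, n_steps, n_sens)
  v_true <- numeric(n_steps)
  v_u <- numeric(n_steps)
  v_H <- numeric(n_steps)
  v_gate <- character(n_steps)
  v_dose <- numeric(n_steps)
  dose_acc <- 0
  fault <- NULL
  ctrl_i <- match(scn$control_sensor, ns)

  k_done <- 0L
  for (k in seq_len(n_steps)) {
    taps <- sensor_read_full(sstate, scn$sensors)
    readings <- taps$display
    gate <- supervise(readings, scn$safety, gate)

    u <- 0
    if (!is.null(u_fun)) {
      if (!is.finite(taps$analog[[ctrl_i]])) {
        fault <- "controller fault: non-finite control reading"
        v_gate[k] <- "TRIP:fault"
        k_done <- k
        break
      }
      res <- u_fun(k, taps$analog, cstate)
      u <- res$u
      cstate <- res$cstate
    }
    H <- if (!is.null(H_cmd)) H_cmd[k] else voltage_to_field(u, scn$actuator)
    if (!is.null(H_cmd)) {
      u <- field_to_voltage(H, scn$actuator)
    }
    if (!gate$power_allowed) H <- 0
    P <- source_power(scn$source, H, f)
    drive <- if (lumped) NA_real_ else P / P_ref

    st <- tryCatch(
      advance_plant(scn, pstate, sstate, P, drive, dt_ctrl),
      mhtsim_plant_fault = function(e) e)
    if (inherits(st, "condition")) {
      fault <- conditionMessage(st)
      k_done <- k
      break
    }

    Tc <- readings[[ctrl_i]]
    if (Tc >= dp$floor_temp) {
      R <- if (Tc >= dp$breakpoint) dp$R_above else dp$R_below
      dose_acc <- dose_acc + dt_ctrl / 60 * R^(dp$breakpoint - Tc)
    }

    M_read[k, ] <- readings
    v_true[k] <- truth0[ctrl_i]
    v_u[k] <- u
    v_H[k] <- H
    v_gate[k] <- if (gate$power_allowed) "ALLOW" else
      paste0("TRIP:", gate$tripped_by)
    v_dose[k] <- dose_acc

    pstate <- st$pstate
    sstate <- st$sstate
    truth0 <- sensor_truth(scn, pstate)
    k_done <- k
  }

  keep <- seq_len(k_done)
  log_df <- data.frame(t_s = (keep - 1L) * dt_ctrl)
  for (j in seq_len(n_sens)) log_df[[paste0("T_", ns[j])]] <- M_read[keep, j]
  log_df$T_true_ctrl <- v_true[keep]
  log_df$u_V <- v_u[keep]
  log_df$H_A_per_m <- v_H[keep]
  log_df$gate <- v_gate[keep]
  log_df$cem43_min <- v_dose[keep]
  structure(log_df,
            class = c("session_log", "data.frame"),
            sensors = ns, control_sensor = scn$control_sensor,
            scenario_name = scn$name, seed = seed,
            trip_count = gate$trip_count, fault = fault)
}

ref_field <- function(src) {
  if (!is.null(src$H_ref)) src$H_ref else 1
}

field_to_voltage <- function(H, map) {
  map$v_zero + pmin(H / map$H_full, 1) * (map$v_full - map$v_zero)
}

#' Run a closed-loop temperature-control session
#'
#' Wires plant, sensors, safety supervisor, PID controller and actuator at
#' the control cadence (default 1 s). Intra-step order is fixed: sensors
#' sample the plant, the supervisor gates, the controller computes the
#' feedback voltage from the control sensor, the actuator maps voltage to
#' field (zero while gated), the sources scale with the field and the
#' plant integrates over the control interval in substeps. Deterministic
#' under a fixed seed.
#'
#' @param scn A [scenario()].
#' @param seed RNG seed (default: the scenario's).
#' @return A `session_log` data frame with columns `t_s`,
#'   `T_<sensor>` (one per sensor), `T_true_ctrl`, `u_V`, `H_A_per_m`,
#'   `gate` (`ALLOW` or `TRIP:<sensor>`) and the running `cem43_min`. A
#'   plant or controller fault truncates the log and is recorded in the
#'   `fault` attribute.
#' @export
run_closed_loop <- function(scn, seed = scn$seed) {
  stopifnot(inherits(scn, "scenario"))
  n_steps <- as.integer(ceiling(scn$duration / scn$controller$sample_interval))
  cfg <- scn$controller
  u_fun <- function(k, readings, cstate) {
    out <- pid_step(cstate, readings[[scn$control_sensor]], cfg)
    list(u = out$u, cstate = out$state)
  }
  run_session(scn, seed, n_steps, u_fun = u_fun)
}

#' Run an open-loop pulse sequence
#'
#' Constant-field pulses with inter-pulse cooldowns, as used for
#' pre-heating conditioning and pulse-response gain estimation. The safety
#' supervisor stays active. The resulting log feeds [identify_fopdt()]
#' and [retune_from_pulses()].
#'
#' @param scn A [scenario()] (its controller is bypassed).
#' @param pulses Data frame with columns `H_A_per_m`, `duration_s` and
#'   optionally `cooldown_s` (cooldown after each pulse, default 60 s).
#' @param lead_in_s Baseline time logged before the first pulse (default 10).
#' @param seed RNG seed.
#' @return A `session_log` as in [run_closed_loop()].
#' @export
run_pulse_sequence <- function(scn, pulses, lead_in_s = 10, seed = scn$seed) {
  stopifnot(inherits(scn, "scenario"), is.data.frame(pulses),
            all(c("H_A_per_m", "duration_s") %in% names(pulses)))
  if (any(pulses$H_A_per_m > scn$actuator$H_cap)) {
    stop("run_pulse_sequence: pulse amplitude exceeds the scenario field cap",
         call. = FALSE)
  }
  cool <- if ("cooldown_s" %in% names(pulses)) pulses$cooldown_s else
    rep(60, nrow(pulses))
  dt <- scn$controller$sample_interval
  H_cmd <- rep(0, round(lead_in_s / dt))
  for (i in seq_len(nrow(pulses))) {
    H_cmd <- c(H_cmd,
               rep(pulses$H_A_per_m[i], round(pulses$duration_s[i] / dt)),
               rep(0, round(cool[i] / dt)))
  }
  run_session(scn, seed, length(H_cmd), H_cmd = H_cmd)
}

#' Grid search over PID gain triples
#'
#' Simulates every gain triple on the scenario, evaluates the performance
#' report, filters by the design criteria and ranks the passing set by
#' settling time, then integrated absolute error, then smaller Kd.
#' Deterministic under the fixed seed.
#'
#' @param scn A [scenario()].
#' @param grid Data frame with columns `Kp`, `Ki`, `Kd`.
#' @param criteria Named limits: `rise_s`, `overshoot_pct`, `settling_s`,
#'   `ss_error_pct`.
#' @param seed RNG seed used for every run.
#' @return List with `table` (one row per triple: gains, metrics, `pass`,
#'   `iae`, ordered best first) and `best` (a [pid_gains()], or `NULL`
#'   when no triple passes).
#' @export
tune_gains_grid <- function(scn, grid,
                            criteria = c(rise_s = 60, overshoot_pct = 5,
                                         settling_s = 300, ss_error_pct = 1),
                            seed = scn$seed) {
  stopifnot(is.data.frame(grid), all(c("Kp", "Ki", "Kd") %in% names(grid)),
            nrow(grid) >= 1L)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    scn_i <- scn
    scn_i$controller$gains <- pid_gains(grid$Kp[i], grid$Ki[i], grid$Kd[i])
    log <- run_closed_loop(scn_i, seed = seed)
    rep <- performance_report(log, scn_i)
    col <- paste0("T_", scn_i$control_sensor)
    iae <- sum(abs(log[[col]] - scn_i$controller$setpoint)) *
      scn_i$controller$sample_interval
    pass <- rep$rise_reached && rep$t_r < criteria[["rise_s"]] &&
      rep$M_p < criteria[["overshoot_pct"]] &&
      rep$settled && rep$t_ss < criteria[["settling_s"]] &&
      !is.na(rep$ss_error_pct) && rep$ss_error_pct < criteria[["ss_error_pct"]]
    data.frame(Kp = grid$Kp[i], Ki = grid$Ki[i], Kd = grid$Kd[i],
               t_r = rep$t_r, t_ss = rep$t_ss, M_p = rep$M_p,
               ss_error_pct = rep$ss_error_pct, cem43 = rep$cem43,
               iae = iae, pass = pass)
  })
  tab <- do.call(rbind, rows)
  ord <- order(!tab$pass, tab$t_ss, tab$iae, tab$Kd)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  best <- if (any(tab$pass)) {
    b <- tab[tab$pass, ][1L, ]
    pid_gains(b$Kp, b$Ki, b$Kd)
  } else NULL
  list(table = tab, best = best)
}

#' Model-based PID retuning from a pulse log
#'
#' Identifies a first-order-plus-dead-time surrogate from the pulse log
#' ([identify_fopdt()]), linearises the actuator-source chain about the
#' drive needed to hold the setpoint, and applies internal-model-control
#' (SIMC) tuning rules to produce a gain triple in controller units.
#'
#' @param scn A [scenario()] providing setpoint, actuator and source.
#' @param pulse_log A pulse-response `session_log`.
#' @param lambda Desired closed-loop time constant, s; default
#'   `max(dead_time, tau_p/8)`.
#' @return A [pid_gains()] object, with the identified model attached as
#'   attribute `model`.
#' @export
retune_from_pulses <- function(scn, pulse_log, lambda = NULL) {
  fit <- identify_fopdt(pulse_log, scn$source)
  K <- fit$K_gain; tau <- fit$tau_p; theta <- fit$dead_time
  dt <- scn$controller$sample_interval
  amap <- scn$actuator
  f <- amap$frequency
  H_ref <- ref_field(scn$source)
  P_ref <- source_power(scn$source, H_ref, f)

  T0 <- if (inherits(scn$plant, "lumped_plant_config")) scn$plant$T0 else
    scn$plant$T_a
  step_C <- scn$controller$setpoint - T0
  P_need <- max(step_C, 0.1 * K * P_ref * 1e-3) / K
  frac_need <- min(sqrt(P_need / P_ref), 1)
  u_op <- amap$v_zero + frac_need * (H_ref / amap$H_full) *
    (amap$v_full - amap$v_zero)
  # local gain of the u -> H -> P -> T chain, degC per V
  dfrac_du <- (amap$H_full / H_ref) / (amap$v_full - amap$v_zero)
  g_u <- K * P_ref * 2 * frac_need * dfrac_du

  if (is.null(lambda)) lambda <- max(theta, tau / 8, dt)
  Kc <- tau / (g_u * (lambda + theta))
  Ti <- min(tau, 4 * (lambda + theta))
  Td <- theta / 2
  gains <- pid_gains(Kc, Kc / Ti, Kc * Td)
  attr(gains, "model") <- fit
  gains
}
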