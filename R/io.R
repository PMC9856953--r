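#' Write a session log to CSV
#'
#' Serialises a session log in the documented schema: columns `t_s`,
#' `T_<sensor>` (one per sensor, degC), `T_true_ctrl`, `u_V`,
#' `H_A_per_m`, `gate` (`ALLOW` or `TRIP:<sensor>`), `cem43_min`;
#' mandatory header row, UTF-8, `.` decimal separator. Output is
#' bit-stable for identical logs and round-trips through
#' [read_session()].
#'
#' @param log A `session_log` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(log, path) {
  log_df <- as.data.frame(log)
  required <- c("t_s", "T_true_ctrl", "u_V", "H_A_per_m", "gate", "cem43_min")
  if (!all(required %in% names(log_df))) {
    stop("write_session: log lacks required columns: ",
         paste(setdiff(required, names(log_df)), collapse = ", "),
         call. = FALSE)
  }
  out <- log_df
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], function(x) sprintf("%.12g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a session log from CSV
#'
#' Parses and validates a file in the session-log schema; columns are
#' matched by header name, so column order is free. Schema violations are
#' reported with the offending column or line.
#'
#' @param path CSV file path.
#' @return A `session_log` data frame.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("read_session: no such file: ", path, call. = FALSE)
  log_df <- utils::read.csv(path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  required <- c("t_s", "T_true_ctrl", "u_V", "H_A_per_m", "gate", "cem43_min")
  missing_cols <- setdiff(required, names(log_df))
  if (length(missing_cols) > 0L) {
    stop("read_session: missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sensor_cols <- setdiff(grep("^T_", names(log_df), value = TRUE), "T_true_ctrl")
  if (length(sensor_cols) == 0L) {
    stop("read_session: no sensor columns (T_<sensor>)", call. = FALSE)
  }
  if (nrow(log_df) >= 2L) {
    dt <- diff(log_df$t_s)
    bad <- which(abs(dt - dt[1L]) > 1e-9)
    if (dt[1L] <= 0 || length(bad) > 0L) {
      stop("read_session: non-uniform time grid at line ",
           if (length(bad) > 0L) bad[1L] + 2L else 2L,
           " (data lines start at 2)", call. = FALSE)
    }
  }
  num_cols <- c("t_s", sensor_cols, "T_true_ctrl", "u_V", "H_A_per_m",
                "cem43_min")
  for (cc in num_cols) {
    if (!is.numeric(log_df[[cc]])) {
      stop("read_session: column ", cc, " is not numeric", call. = FALSE)
    }
  }
  ordered <- c("t_s", sensor_cols, "T_true_ctrl", "u_V", "H_A_per_m",
               "gate", "cem43_min")
  log_df <- log_df[ordered]
  structure(log_df, class = c("session_log", "data.frame"),
            sensors = sub("^T_", "", sensor_cols))
}

#' Extract a sensor trace from a session log
#'
#' @param log A `session_log`.
#' @param sensor Sensor id (default: the log's control sensor if known,
#'   else the first sensor column).
#' @return A [temperature_trace()].
#' @export
trace_from_log <- function(log, sensor = NULL) {
  log_df <- as.data.frame(log)
  if (is.null(sensor)) {
    sensor <- attr(log, "control_sensor")
    if (is.null(sensor)) {
      sensor <- sub("^T_", "",
                    setdiff(grep("^T_", names(log_df), value = TRUE),
                            "T_true_ctrl")[1L])
    }
  }
  col <- paste0("T_", sensor)
  if (!col %in% names(log_df)) {
    stop("trace_from_log: no sensor column '", col, "'", call. = FALSE)
  }
  temperature_trace(log_df$t_s, log_df[[col]], sensor)
}

# ---- scenario YAML ---------------------------------------------------------

check_keys <- function(x, allowed, required, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0L) {
    stop("load_scenario: unknown key(s) at ", where, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(required, names(x))
  if (length(miss) > 0L) {
    stop("load_scenario: missing required key(s) at ", where, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

get_or <- function(x, key, default) if (is.null(x[[key]])) default else x[[key]]

parse_source <- function(s) {
  check_keys(s, c("type", "SLP_ref_W_per_g", "H_ref_kA_per_m",
                  "cFe_mg_per_mL", "sigma_s_mm", "SAR_Cu_W_per_g",
                  "mass_g", "rho_Cu_g_per_m3", "sigma_e_S_per_m", "r_m",
                  "prefactor"),
             "type", "source")
  switch(s$type,
    mnp = mnp_source(SLP_ref = s$SLP_ref_W_per_g,
                     H_ref = s$H_ref_kA_per_m * 1e3,
                     cFe = s$cFe_mg_per_mL * 1e3,
                     sigma_s = get_or(s, "sigma_s_mm", 3) * 1e-3),
    cu = cu_source(SAR_Cu = s$SAR_Cu_W_per_g,
                   mass = get_or(s, "mass_g", 0.104),
                   rho_Cu = get_or(s, "rho_Cu_g_per_m3", 8.96e6),
                   H_ref = s$H_ref_kA_per_m * 1e3),
    eddy = eddy_params(sigma_e = s$sigma_e_S_per_m, r = s$r_m,
                       prefactor = get_or(s, "prefactor", 1)),
    stop("load_scenario: unknown source type '", s$type, "'", call. = FALSE))
}

parse_plant <- function(p) {
  if (is.null(p$type)) stop("load_scenario: missing plant.type", call. = FALSE)
  if (p$type == "lumped") {
    check_keys(p, c("type", "K_gain_C_per_W_m3", "tau_p_s", "dead_time_s",
                    "T0_C", "coupling_per_s", "core_tau_s", "T_core0_C"),
               c("type", "K_gain_C_per_W_m3", "tau_p_s", "T0_C"), "plant")
    lumped_plant_config(K_gain = p$K_gain_C_per_W_m3, tau_p = p$tau_p_s,
                        dead_time = get_or(p, "dead_time_s", 0),
                        T0 = p$T0_C,
                        coupling = get_or(p, "coupling_per_s", 0),
                        core_tau = get_or(p, "core_tau_s", 600),
                        T_core0 = get_or(p, "T_core0_C", p$T0_C))
  } else if (p$type == "radial") {
    check_keys(p, c("type", "geometry", "R_max_mm", "n_cells",
                    "k_W_per_m_C", "rho_kg_per_m3", "c_J_per_kg_C",
                    "omega_b_per_s", "rho_b_c_b_J_per_m3_C", "T_a_C",
                    "Q_met_W_per_m3", "boundary", "source_peak_W_per_m3",
                    "source_sigma_mm"),
               c("type", "geometry", "R_max_mm", "n_cells", "k_W_per_m_C",
                 "rho_kg_per_m3", "c_J_per_kg_C", "T_a_C",
                 "source_peak_W_per_m3"), "plant")
    bc <- get_or(p, "boundary", list(type = "fixed_T", T_b_C = p$T_a_C))
    boundary <- if (bc$type == "fixed_T") {
      list(type = "fixed_T", T_b = get_or(bc, "T_b_C", p$T_a_C))
    } else {
      list(type = "convective", h = bc$h_W_per_m2_C, T_inf = bc$T_inf_C)
    }
    cfg <- radial_plant_config(geometry = p$geometry,
                               R_max = p$R_max_mm * 1e-3,
                               n_cells = p$n_cells, k = p$k_W_per_m_C,
                               rho = p$rho_kg_per_m3, c_p = p$c_J_per_kg_C,
                               omega_b = get_or(p, "omega_b_per_s", 0),
                               rho_b_c_b = get_or(p, "rho_b_c_b_J_per_m3_C", 3.8e6),
                               T_a = p$T_a_C,
                               Q_met = get_or(p, "Q_met_W_per_m3", 0),
                               boundary = boundary)
    cfg$source_field <- gaussian_source_profile(
      cfg, p$source_peak_W_per_m3, get_or(p, "source_sigma_mm", 3) * 1e-3)
    cfg
  } else {
    stop("load_scenario: unknown plant type '", p$type, "'", call. = FALSE)
  }
}

#' Load a scenario from YAML or by preset name
#'
#' Reads and validates a scenario description (strict schema: unknown keys
#' are rejected with their key path, units are explicit in key names).
#' Bare names are resolved against the shipped presets; see
#' [list_scenarios()].
#'
#' @param path_or_name Path to a YAML file, or a preset name such as
#'   `"gel_cu"`, `"liver_single_44"`, `"canine_45_tuned"`.
#' @return A [scenario()] object.
#' @export
#' @examples
#' scn <- load_scenario("gel_cu")
#' scn$controller$gains
load_scenario <- function(path_or_name) {
  path <- if (file.exists(path_or_name)) path_or_name else {
    p <- system.file("extdata", "scenarios",
                     paste0(path_or_name, ".yaml"), package = "mhtsim")
    if (!nzchar(p)) {
      stop("load_scenario: no file or preset '", path_or_name, "'; presets: ",
           paste(list_scenarios(), collapse = ", "), call. = FALSE)
    }
    p
  }
  y <- yaml::read_yaml(path)
  check_keys(y, c("name", "duration_s", "seed", "substep_s", "controller",
                  "actuator", "source", "plant", "sensors", "safety"),
             c("name", "duration_s", "controller", "actuator", "source",
               "plant", "sensors", "safety"), "top level")

  ctl <- y$controller
  check_keys(ctl, c("kp", "ki", "kd", "setpoint_C", "sample_interval_s",
                    "u_min_V", "u_max_V", "derivative_filter_tau_s",
                    "input_filter_tau_s"),
             c("kp", "ki", "kd", "setpoint_C"), "controller")
  controller <- controller_config(
    gains = pid_gains(ctl$kp, ctl$ki, ctl$kd),
    setpoint = ctl$setpoint_C,
    sample_interval = get_or(ctl, "sample_interval_s", 1),
    u_min = get_or(ctl, "u_min_V", 0),
    u_max = get_or(ctl, "u_max_V", 5),
    derivative_filter_tau = get_or(ctl, "derivative_filter_tau_s", 2),
    input_filter_tau = get_or(ctl, "input_filter_tau_s", 0))

  act <- y$actuator
  check_keys(act, c("v_zero_V", "v_full_V", "H_full_kA_per_m",
                    "frequency_kHz", "H_cap_kA_per_m"),
             c("v_full_V", "H_full_kA_per_m", "frequency_kHz"), "actuator")
  amap <- actuator_map(v_zero = get_or(act, "v_zero_V", 0),
                       v_full = act$v_full_V,
                       H_full = act$H_full_kA_per_m * 1e3,
                       frequency = act$frequency_kHz * 1e3,
                       H_cap = get_or(act, "H_cap_kA_per_m",
                                      act$H_full_kA_per_m) * 1e3)

  sen <- y$sensors
  check_keys(sen, c("names", "map", "control", "lag_tau_s", "noise_sd_C",
                    "bias_C", "resolution_C"),
             c("names", "map", "control"), "sensors")
  sensors <- sensor_config(names = unlist(sen$names),
                           lag_tau = get_or(sen, "lag_tau_s", 0.05),
                           noise_sd = get_or(sen, "noise_sd_C", 0.05),
                           bias = get_or(sen, "bias_C", 0),
                           resolution = get_or(sen, "resolution_C", 0.1))
  sensor_map <- unlist(sen$map)

  saf <- y$safety
  check_keys(saf, c("thresholds_C", "deadband_C"), "thresholds_C", "safety")
  safety <- safety_config(thresholds = unlist(saf$thresholds_C),
                          deadband = get_or(saf, "deadband_C", 0))

  scenario(name = y$name, duration = y$duration_s,
           controller = controller, actuator = amap,
           source = parse_source(y$source), plant = parse_plant(y$plant),
           sensors = sensors, sensor_map = sensor_map, safety = safety,
           control_sensor = sen$control,
           seed = get_or(y, "seed", 7L),
           substep = get_or(y, "substep_s", 0.1))
}

#' List shipped scenario presets
#'
#' @return Character vector of preset names accepted by [load_scenario()].
#' @export
list_scenarios <- function() {
  dir_path <- system.file("extdata", "scenarios", package = "mhtsim")
  sub("\\.yaml$", "", list.files(dir_path, pattern = "\\.yaml$"))
}
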