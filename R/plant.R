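#' Lumped two-node thermal plant
#'
#' Reduced-order surrogate for the full 3-D heat-transfer models behind a
#' controlled heating experiment: a first-order-plus-dead-time (FOPDT)
#' target node, optionally exchanging heat with a slower "core" node
#' (body-core or periphery temperature). The target node obeys
#' `dT/dt = (K_gain * P_delayed + T0 - T)/tau_p + coupling * (T_core - T)`,
#' where `P_delayed` is the applied power density transported by
#' `dead_time` seconds. `K_gain * P` is the steady-state temperature the
#' node would reach at constant drive; for near-field sensor placement
#' (millimetres from a wire or particle deposit) this virtual asymptote is
#' far above any temperature the controlled loop ever visits, so
#' `K_gain` and `tau_p` act as joint calibration constants of the
#' surrogate rather than bulk tissue properties.
#'
#' @param K_gain Steady-state gain at the target node, degC per (W/m^3).
#' @param tau_p Target-node time constant, s.
#' @param dead_time Transport delay on the power input, s (default 0).
#' @param T0 Baseline (zero-power equilibrium) temperature, degC.
#' @param coupling Target-core exchange rate, 1/s (default 0).
#' @param core_tau Core-node relaxation time, s (default 600).
#' @param T_core0 Core-node baseline, degC (default `T0`).
#' @return An object of class `lumped_plant_config`.
#' @export
lumped_plant_config <- function(K_gain, tau_p, dead_time = 0, T0,
                                coupling = 0, core_tau = 600,
                                T_core0 = T0) {
  stopifnot(is.finite(K_gain), tau_p > 0, dead_time >= 0, is.finite(T0),
            coupling >= 0, core_tau > 0, is.finite(T_core0))
  structure(list(K_gain = K_gain, tau_p = tau_p, dead_time = dead_time,
                 T0 = T0, coupling = coupling, core_tau = core_tau,
                 T_core0 = T_core0),
            class = c("lumped_plant_config", "plant_config"))
}

#' 1-D radial Pennes bioheat plant
#'
#' Finite-volume discretisation of the Pennes bioheat balance in a sphere
#' or infinite cylinder:
#' `rho c dT/dt = (1/r^g) d/dr (r^g k dT/dr) + rho_b c_b omega_b (T_a - T)
#'  + Q_met + drive * source_field`
#' with `g = 2` (sphere) or `1` (cylinder), a symmetry (zero-flux)
#' condition at `r = 0` and either a fixed-temperature or convective
#' boundary at `R_max`. The grid is cell-centred: cell `i` spans
#' `[(i-1) dr, i dr]` with its node at `(i - 1/2) dr`, `dr = R_max/n_cells`.
#'
#' @param geometry `"sphere"` or `"cylinder"`.
#' @param R_max Domain radius, m.
#' @param n_cells Number of cells (>= 8).
#' @param k Thermal conductivity, W/(m degC).
#' @param rho Tissue density, kg/m^3.
#' @param c_p Tissue specific heat, J/(kg degC).
#' @param omega_b Blood perfusion rate, 1/s (0 for ex vivo tissue).
#' @param rho_b_c_b Blood volumetric heat capacity, J/(m^3 degC).
#' @param T_a Arterial temperature, degC.
#' @param Q_met Metabolic heat source, W/m^3.
#' @param boundary List: `list(type = "fixed_T", T_b = ...)` or
#'   `list(type = "convective", h = ..., T_inf = ...)` (h in W/(m^2 degC)).
#' @param source_field Power density per cell at unit drive, W/m^3
#'   (length `n_cells`, or a single value recycled).
#' @return An object of class `radial_plant_config`.
#' @export
radial_plant_config <- function(geometry = c("sphere", "cylinder"),
                                R_max, n_cells, k, rho, c_p,
                                omega_b = 0, rho_b_c_b = 3.8e6,
                                T_a = 37, Q_met = 0,
                                boundary = list(type = "fixed_T", T_b = T_a),
                                source_field = 0) {
  geometry <- match.arg(geometry)
  stopifnot(R_max > 0, n_cells >= 8, k > 0, rho > 0, c_p > 0,
            omega_b >= 0, rho_b_c_b > 0, is.finite(T_a), is.finite(Q_met))
  n_cells <- as.integer(n_cells)
  if (!is.list(boundary) || is.null(boundary$type) ||
      !boundary$type %in% c("fixed_T", "convective")) {
    stop("radial_plant_config: boundary must be fixed_T or convective",
         call. = FALSE)
  }
  src <- rep_len(as.numeric(source_field), n_cells)
  if (any(src < 0)) stop("radial_plant_config: source_field must be >= 0",
                         call. = FALSE)
  structure(list(geometry = geometry, R_max = R_max, n_cells = n_cells,
                 k = k, rho = rho, c_p = c_p, omega_b = omega_b,
                 rho_b_c_b = rho_b_c_b, T_a = T_a, Q_met = Q_met,
                 boundary = boundary, source_field = src),
            class = c("radial_plant_config", "plant_config"))
}

#' Gaussian radial source profile
#'
#' Power-density profile for a particle deposit centred at the origin with
#' Gaussian spread `sigma_s`, evaluated at the cell centres of a radial
#' plant grid and scaled so that the peak equals `P_peak`.
#'
#' @param cfg A [radial_plant_config()].
#' @param P_peak Peak power density at the centre, W/m^3.
#' @param sigma_s Gaussian standard deviation, m.
#' @return Numeric vector of length `cfg$n_cells`.
#' @export
gaussian_source_profile <- function(cfg, P_peak, sigma_s = 3e-3) {
  r <- cell_centers(cfg)
  P_peak * exp(-r^2 / (2 * sigma_s^2))
}

cell_centers <- function(cfg) {
  dr <- cfg$R_max / cfg$n_cells
  (seq_len(cfg$n_cells) - 0.5) * dr
}

#' Initialise plant state
#'
#' @param cfg A plant configuration.
#' @param T_init Initial temperature(s), degC; defaults to the baseline
#'   (`T0`/`T_core0` for lumped, `T_a` for radial).
#' @return An object of class `plant_state` holding node temperatures, the
#'   elapsed time, the dead-time input buffer (lumped) and a solver cache.
#' @export
plant_init <- function(cfg, T_init = NULL) {
  UseMethod("plant_init")
}

#' @export
plant_init.lumped_plant_config <- function(cfg, T_init = NULL) {
  temps <- if (is.null(T_init)) c(target = cfg$T0, core = cfg$T_core0) else {
    stopifnot(length(T_init) %in% c(1L, 2L))
    if (length(T_init) == 1L) c(target = T_init, core = cfg$T_core0)
    else c(target = T_init[1L], core = T_init[2L])
  }
  structure(list(temps = temps, time = 0, delay_buffer = numeric(0),
                 delay_dt = NA_real_, cache = new.env(parent = emptyenv())),
            class = "plant_state")
}

#' @export
plant_init.radial_plant_config <- function(cfg, T_init = NULL) {
  temps <- if (is.null(T_init)) rep(cfg$T_a, cfg$n_cells) else
    rep_len(as.numeric(T_init), cfg$n_cells)
  structure(list(temps = temps, time = 0,
                 cache = new.env(parent = emptyenv())),
            class = "plant_state")
}

# transport delay: push the new input, return the input dead_time ago
delay_input <- function(state, P, dt, dead_time) {
  if (dead_time <= 0) return(list(state = state, P = P))
  n_delay <- max(1L, as.integer(round(dead_time / dt)))
  if (!identical(state$delay_dt, dt) ||
      length(state$delay_buffer) != n_delay) {
    state$delay_buffer <- rep(0, n_delay)  # assume zero drive before start
    state$delay_dt <- dt
  }
  buf <- c(state$delay_buffer, P)
  state$delay_buffer <- buf[-1L]
  list(state = state, P = buf[1L])
}

#' Advance the lumped plant by one step
#'
#' Exact exponential update of the linear two-node system under
#' piecewise-constant drive; unconditionally stable for any step size.
#'
#' @param state A `plant_state` from [plant_init()].
#' @param P Applied power density at the target node, W/m^3.
#' @param dt Step size, s.
#' @param cfg The [lumped_plant_config()].
#' @return Updated `plant_state`.
#' @export
step_lumped <- function(state, P, dt, cfg) {
  stopifnot(inherits(state, "plant_state"), dt > 0, is.finite(P))
  d <- delay_input(state, P, dt, cfg$dead_time)
  state <- d$state
  P_eff <- d$P

  if (cfg$coupling == 0) {
    # two independent scalar exponentials
    Tt <- state$temps[["target"]]
    Tc <- state$temps[["core"]]
    a1 <- exp(-dt / cfg$tau_p)
    Tt_ss <- cfg$T0 + cfg$K_gain * P_eff
    state$temps[["target"]] <- Tt_ss + (Tt - Tt_ss) * a1
    a2 <- exp(-dt / cfg$core_tau)
    state$temps[["core"]] <- cfg$T_core0 + (Tc - cfg$T_core0) * a2
  } else {
    key <- sprintf("eig_%g", dt)
    cache <- state$cache
    if (is.null(cache[[key]])) {
      A <- matrix(c(-(1 / cfg$tau_p + cfg$coupling), cfg$coupling,
                    cfg$coupling, -(1 / cfg$core_tau + cfg$coupling)),
                  2L, 2L)
      ev <- eigen(A, symmetric = TRUE)
      cache[[key]] <- list(A = A, V = ev$vectors,
                           expl = exp(ev$values * dt))
    }
    eg <- cache[[key]]
    b <- c((cfg$K_gain * P_eff + cfg$T0) / cfg$tau_p,
           cfg$T_core0 / cfg$core_tau)
    x_ss <- -solve(eg$A, b)
    x <- as.numeric(state$temps)
    z <- crossprod(eg$V, x - x_ss) * eg$expl
    x_new <- as.numeric(x_ss + eg$V %*% z)
    state$temps <- c(target = x_new[1L], core = x_new[2L])
  }
  state$time <- state$time + dt
  state
}

# assemble the symmetric finite-volume operator and capacity vector
radial_operator <- function(cfg) {
  n <- cfg$n_cells
  dr <- cfg$R_max / n
  faces <- seq_len(n - 1L) * dr           # interior faces
  if (cfg$geometry == "sphere") {
    area <- function(r) 4 * pi * r^2
    vol <- 4 / 3 * pi * ((seq_len(n) * dr)^3 - ((seq_len(n) - 1L) * dr)^3)
  } else {
    area <- function(r) 2 * pi * r        # per unit length
    vol <- pi * ((seq_len(n) * dr)^2 - ((seq_len(n) - 1L) * dr)^2)
  }
  G <- cfg$k * area(faces) / dr           # interior conductances
  diag_K <- numeric(n)
  diag_K[seq_len(n - 1L)] <- diag_K[seq_len(n - 1L)] + G
  diag_K[2L:n] <- diag_K[2L:n] + G
  # boundary at R_max
  bc <- cfg$boundary
  if (bc$type == "fixed_T") {
    G_b <- cfg$k * area(cfg$R_max) / (dr / 2)
    T_b <- bc$T_b
  } else {
    G_b <- bc$h * area(cfg$R_max)
    T_b <- bc$T_inf
  }
  diag_K[n] <- diag_K[n] + G_b
  perf <- vol * cfg$rho_b_c_b * cfg$omega_b
  list(n = n, vol = vol, G = G, diag_K = diag_K + perf, G_b = G_b,
       T_b = T_b, perf = perf, cap = vol * cfg$rho * cfg$c_p)
}

radial_matrix <- function(op, inv_dt) {
  n <- op$n
  A <- matrix(0, n, n)
  idx <- seq_len(n - 1L)
  A[cbind(idx, idx + 1L)] <- -op$G
  A[cbind(idx + 1L, idx)] <- -op$G
  diag(A) <- op$diag_K + op$cap * inv_dt
  A
}

#' Advance the radial Pennes plant by one implicit step
#'
#' Backward-Euler finite-volume update; the symmetric positive-definite
#' system is Cholesky-factorised once per step size and the factor reused.
#' `dt = Inf` solves directly for the steady state (only valid when
#' perfusion or a boundary condition anchors the temperature level).
#'
#' @param state A `plant_state` from [plant_init()].
#' @param drive Scalar multiplier on `cfg$source_field`.
#' @param dt Step size in s, or `Inf` for the steady state.
#' @param cfg The [radial_plant_config()].
#' @return Updated `plant_state`.
#' @export
step_radial <- function(state, drive, dt, cfg) {
  stopifnot(inherits(state, "plant_state"), dt > 0, is.finite(drive),
            drive >= 0)
  cache <- state$cache
  if (is.null(cache$op)) cache$op <- radial_operator(cfg)
  op <- cache$op
  inv_dt <- if (is.finite(dt)) 1 / dt else 0
  key <- sprintf("chol_%g", inv_dt)
  if (is.null(cache[[key]])) {
    A <- radial_matrix(op, inv_dt)
    R <- tryCatch(chol(A), error = function(e) {
      stop(structure(class = c("mhtsim_plant_fault", "error", "condition"),
                     list(message = paste("step_radial: singular system -",
                                          conditionMessage(e)),
                          call = sys.call())))
    })
    cache[[key]] <- R
  }
  R <- cache[[key]]
  rhs <- op$cap * inv_dt * state$temps +
    op$vol * (cfg$Q_met + drive * cfg$source_field) +
    op$perf * cfg$T_a
  rhs[op$n] <- rhs[op$n] + op$G_b * op$T_b
  Tnew <- backsolve(R, forwardsolve(t(R), rhs))
  state$temps <- as.numeric(Tnew)
  state$time <- state$time + if (is.finite(dt)) dt else 0
  state
}

#' Temperature at a position or node
#'
#' Linear interpolation between cell centres (radial plants) or direct
#' node lookup (lumped plants). Positions between the domain edge and the
#' nearest cell centre use the nearest centre's value.
#'
#' @param state A `plant_state`.
#' @param cfg The matching plant configuration.
#' @param position For radial plants a radius in m (within `[0, R_max]`);
#'   for lumped plants `"target"`, `"core"`, or node index 1/2.
#' @return Temperature in degC.
#' @export
temperature_at <- function(state, cfg, position) {
  stopifnot(inherits(state, "plant_state"))
  if (inherits(cfg, "lumped_plant_config")) {
    if (is.character(position)) {
      if (!position %in% names(state$temps)) {
        stop("temperature_at: unknown node '", position, "'", call. = FALSE)
      }
      return(state$temps[[position]])
    }
    stopifnot(position %in% c(1, 2))
    return(as.numeric(state$temps[position]))
  }
  r <- cell_centers(cfg)
  if (position < 0 || position > cfg$R_max) {
    stop("temperature_at: position outside the domain", call. = FALSE)
  }
  stats::approx(r, state$temps, xout = position, rule = 2)$y
}

# shift a sampled series by a (possibly fractional) number of samples,
# zero-padding the past
shift_series <- function(x, shift_samples) {
  n <- length(x)
  if (shift_samples <= 0) return(x)
  lo <- floor(shift_samples)
  frac <- shift_samples - lo
  xlo <- c(rep(0, min(lo, n)), x)[seq_len(n)]
  if (frac == 0) return(xlo)
  xhi <- c(rep(0, min(lo + 1, n)), x)[seq_len(n)]
  (1 - frac) * xlo + frac * xhi
}

# exact discrete response of a FOPDT system to a sampled input held
# constant over each interval
fopdt_response <- function(P, dt, K, tau, theta, T0) {
  a <- exp(-dt / tau)
  P_del <- shift_series(P, theta / dt)
  # y[k+1] = a y[k] + (1-a) K P_del[k]; y[1] = 0
  drive <- (1 - a) * K * P_del
  n <- length(P)
  y <- c(0, stats::filter(drive[-n], a, method = "recursive"))
  T0 + y
}

#' Identify a first-order-plus-dead-time model from a pulse log
#'
#' Fits gain, time constant and transport delay of a FOPDT response to a
#' session log containing one or more constant-power pulses with pre/post
#' baseline, by least squares on the exact discrete step response. This is
#' the desk equivalent of the short (<30 s) pre-heating conditioning
#' pulses used to estimate initial controller gains in vivo.
#'
#' @param pulse_log A session log (data frame with `t_s`, temperature and
#'   `H_A_per_m` columns) from [run_pulse_sequence()] or [read_session()].
#' @param source The heat source used in the session ([mnp_source()] or
#'   [cu_source()]); converts the logged field into applied power density.
#' @param sensor Temperature column to fit. Defaults to the true
#'   control-point temperature column if present, else the first sensor.
#' @param theta_max Upper bound on the dead time, s (default 10).
#' @return List with `K_gain` (degC per W/m^3), `tau_p` (s), `dead_time`
#'   (s) and `rms` (residual RMS, degC).
#' @export
identify_fopdt <- function(pulse_log, source, sensor = NULL,
                           theta_max = 10) {
  log_df <- as.data.frame(pulse_log)
  if (!all(c("t_s", "H_A_per_m") %in% names(log_df))) {
    stop("identify_fopdt: log lacks t_s/H_A_per_m columns", call. = FALSE)
  }
  if (is.null(sensor)) {
    sensor <- if ("T_true_ctrl" %in% names(log_df)) "T_true_ctrl" else
      grep("^T_", names(log_df), value = TRUE)[1L]
  }
  if (!sensor %in% names(log_df)) {
    stop("identify_fopdt: no column '", sensor, "' in log", call. = FALSE)
  }
  tt <- log_df$t_s
  dt <- tt[2L] - tt[1L]
  y <- log_df[[sensor]]
  P <- source_power(source, log_df$H_A_per_m)

  on_idx <- which(P > 0)
  if (length(on_idx) == 0L) {
    stop("identify_fopdt: no pulse detected (zero drive throughout)",
         call. = FALSE)
  }
  pre <- seq_len(max(on_idx[1L] - 1L, 1L))
  T0 <- stats::median(y[pre])
  dT_max <- max(y) - T0
  if (dT_max <= 10 * .Machine$double.eps + 1e-6) {
    stop("identify_fopdt: no detectable temperature response to the pulse",
         call. = FALSE)
  }

  sse <- function(par) {
    K <- exp(par[1L]); tau <- exp(par[2L]); theta <- par[3L]
    yhat <- fopdt_response(P, dt, K, tau, theta, T0)
    sum((yhat - y)^2)
  }
  pulse_dur <- length(on_idx) * dt
  P_on <- max(P)
  best <- NULL
  for (tau0 in unique(pmax(c(pulse_dur / 3, pulse_dur, 3 * pulse_dur), dt))) {
    K0 <- dT_max / (P_on * (1 - exp(-pulse_dur / tau0)))
    fit <- stats::optim(c(log(K0), log(tau0), min(1, theta_max)), sse,
                        method = "L-BFGS-B",
                        lower = c(log(K0) - 12, log(dt / 10), 0),
                        upper = c(log(K0) + 12, log(1e6), theta_max),
                        control = list(maxit = 500))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(K_gain = exp(best$par[1L]), tau_p = exp(best$par[2L]),
       dead_time = best$par[3L],
       rms = sqrt(best$value / length(y)))
}
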