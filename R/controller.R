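#' PID gain triple
#'
#' Gains of the discrete temperature-to-voltage control law. Units follow
#' the hardware signal chain: the controller reads degrees Celsius and
#' writes a feedback voltage, so `Kp` is V/degC, `Ki` is V/(degC s) and
#' `Kd` is V s/degC.
#'
#' @param Kp,Ki,Kd Non-negative finite gains.
#' @return An object of class `pid_gains`.
#' @export
#' @examples
#' pid_gains(0.23, 1e-4, 2.84)  # tuned gel-phantom preset
pid_gains <- function(Kp, Ki = 0, Kd = 0) {
  g <- c(Kp = Kp, Ki = Ki, Kd = Kd)
  if (!all(is.finite(g)) || any(g < 0)) {
    stop("pid_gains: gains must be finite and non-negative", call. = FALSE)
  }
  structure(list(Kp = Kp, Ki = Ki, Kd = Kd), class = "pid_gains")
}

#' Controller configuration
#'
#' Configuration of the discrete positional PID law. The integral is a
#' backward-Euler rectangle sum; the derivative acts on the (filtered)
#' measurement rather than the error, which avoids derivative kick when
#' the setpoint changes; anti-windup is by conditional integration: the
#' integrator freezes whenever the unclamped output is outside the voltage
#' limits and integrating would push it further outside.
#'
#' @param gains A [pid_gains()] object.
#' @param setpoint Target temperature T_ref in degC.
#' @param sample_interval Control interval in s (default 1, the logging
#'   cadence of the device).
#' @param u_min,u_max Output voltage limits in V. The hardware full scale
#'   is 0--5 V; scenarios typically cap at the calibrated field window
#'   (e.g. 1.25 V).
#' @param derivative_filter_tau First-order filter time constant for the
#'   measurement derivative, in s (default 2).
#' @param input_filter_tau First-order low-pass on the measured signal
#'   before the control law, in s (default 0 = none). Suppresses
#'   high-frequency sensor noise before it reaches the proportional and
#'   derivative terms, the role played by the digital signal processing
#'   stage of the hardware controller.
#' @param antiwindup Anti-windup strategy; only `"conditional_integration"`
#'   is implemented.
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(gains, setpoint, sample_interval = 1,
                              u_min = 0, u_max = 5,
                              derivative_filter_tau = 2,
                              input_filter_tau = 0,
                              antiwindup = "conditional_integration") {
  if (!inherits(gains, "pid_gains")) stop("gains must be pid_gains", call. = FALSE)
  stopifnot(is.finite(setpoint), sample_interval > 0,
            is.finite(u_min), is.finite(u_max),
            derivative_filter_tau >= 0, input_filter_tau >= 0)
  if (!(u_min < u_max)) stop("controller_config: u_min must be < u_max", call. = FALSE)
  antiwindup <- match.arg(antiwindup, "conditional_integration")
  structure(list(gains = gains, setpoint = setpoint,
                 sample_interval = sample_interval,
                 u_min = u_min, u_max = u_max,
                 derivative_filter_tau = derivative_filter_tau,
                 input_filter_tau = input_filter_tau,
                 antiwindup = antiwindup),
            class = "controller_config")
}

#' Zeroed controller state
#'
#' @param cfg A [controller_config()]; the last output is initialised to
#'   its lower voltage limit.
#' @return An object of class `controller_state` with a zero integrator,
#'   cleared derivative memory and `last_output = u_min`.
#' @export
pid_reset <- function(cfg) {
  structure(list(integral_acc = 0, prev_measurement = NA_real_,
                 prev_derivative = 0, last_output = cfg$u_min),
            class = "controller_state")
}

#' One discrete PID control step
#'
#' Computes the feedback voltage from one temperature measurement:
#' `e = setpoint - measured`;
#' `u_raw = Kp e + Ki * integral + Kd * d(filtered measurement)/dt`
#' (derivative negated so that a rising measurement reduces the output);
#' `u = clamp(u_raw, u_min, u_max)`. The integrator candidate is accepted
#' only when it does not push an already-saturated output further outside
#' the limits (conditional integration).
#'
#' @param state A `controller_state` from [pid_reset()] or a previous step.
#' @param measured Measured temperature in degC. A non-finite measurement
#'   is a controller fault and raises an error of class
#'   `mhtsim_controller_fault` (the engine maps this to power-down).
#' @param cfg A [controller_config()].
#' @return List with `state` (updated) and `u` (output voltage in V).
#' @export
#' @examples
#' cfg <- controller_config(pid_gains(1), setpoint = 25, u_min = 0, u_max = 5)
#' pid_step(pid_reset(cfg), measured = 23, cfg)$u  # 2 V, pure proportional
pid_step <- function(state, measured, cfg) {
  if (!inherits(state, "controller_state")) {
    stop("pid_step: state must be a controller_state", call. = FALSE)
  }
  if (!is.numeric(measured) || length(measured) != 1L || !is.finite(measured)) {
    stop(structure(class = c("mhtsim_controller_fault", "error", "condition"),
                   list(message = "pid_step: non-finite measurement",
                        call = sys.call())))
  }
  g <- cfg$gains
  dt <- cfg$sample_interval

  # optional input low-pass (measurement conditioning)
  tau_m <- cfg$input_filter_tau
  if (tau_m > 0 && !is.na(state$prev_measurement)) {
    a_m <- exp(-dt / tau_m)
    measured <- a_m * state$prev_measurement + (1 - a_m) * measured
  }
  e <- cfg$setpoint - measured

  # derivative on measurement, first-order filtered; first step has no memory
  raw_d <- if (is.na(state$prev_measurement)) 0 else
    (measured - state$prev_measurement) / dt
  tau_f <- cfg$derivative_filter_tau
  alpha <- if (tau_f > 0) exp(-dt / tau_f) else 0
  d_f <- alpha * state$prev_derivative + (1 - alpha) * raw_d

  int_cand <- state$integral_acc + e * dt
  u_raw <- g$Kp * e + g$Ki * int_cand - g$Kd * d_f
  int_new <- int_cand
  if ((u_raw > cfg$u_max && e > 0) || (u_raw < cfg$u_min && e < 0)) {
    int_new <- state$integral_acc  # freeze: integrating pushes further outside
    u_raw <- g$Kp * e + g$Ki * int_new - g$Kd * d_f
  }
  u <- min(max(u_raw, cfg$u_min), cfg$u_max)

  state$integral_acc <- int_new
  state$prev_measurement <- measured
  state$prev_derivative <- d_f
  state$last_output <- u
  list(state = state, u = u)
}
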