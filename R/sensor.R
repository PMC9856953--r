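#' Fiber-optic multi-sensor probe model
#'
#' Models a multi-point fiber-optic temperature probe: each sensor applies
#' a first-order lag to the true local temperature, a fixed per-sensor
#' bias within the probe accuracy band, zero-mean Gaussian read noise, and
#' quantisation to the display resolution (round half away from zero).
#' The reference probe carries four GaAs sensors 2 cm apart with accuracy
#' +/-0.3 degC, resolution 0.1 degC and response time under 100 ms.
#'
#' @param names Character vector of sensor identifiers.
#' @param lag_tau First-order response time constant, s (<= 0.1 for the
#'   reference probe; 0 disables the lag). Scalar or one per sensor.
#' @param noise_sd Read-noise standard deviation, degC (default 0.02,
#'   well below the display resolution, as for fiber-optic conditioners).
#' @param bias Fixed per-sensor offset, degC, each within +/-0.3. `NULL`
#'   draws one offset per sensor uniformly in the accuracy band when the
#'   probe state is initialised.
#' @param resolution Display resolution, degC (default 0.1).
#' @return An object of class `sensor_config`.
#' @export
sensor_config <- function(names, lag_tau = 0.05, noise_sd = 0.02,
                          bias = 0, resolution = 0.1) {
  stopifnot(is.character(names), length(names) >= 1L, !anyDuplicated(names))
  n <- length(names)
  lag_tau <- rep_len(lag_tau, n)
  stopifnot(all(lag_tau >= 0), resolution > 0, noise_sd >= 0)
  if (!is.null(bias)) {
    bias <- rep_len(bias, n)
    if (any(abs(bias) > 0.3 + 1e-12)) {
      stop("sensor_config: |bias| must be <= 0.3 degC", call. = FALSE)
    }
  }
  structure(list(names = names, lag_tau = lag_tau, noise_sd = noise_sd,
                 bias = bias, resolution = resolution),
            class = "sensor_config")
}

#' Initialise sensor state
#'
#' Sets the lag filters to the given true temperatures and draws the
#' per-sensor bias if the configuration left it free. Uses the current
#' RNG stream, so seed the session before calling for reproducibility.
#'
#' @param cfg A [sensor_config()].
#' @param true_temps Initial true temperature per sensor, degC.
#' @return An object of class `sensor_state`.
#' @export
sensor_init <- function(cfg, true_temps) {
  n <- length(cfg$names)
  true_temps <- rep_len(true_temps, n)
  bias <- if (is.null(cfg$bias)) stats::runif(n, -0.3, 0.3) else cfg$bias
  structure(list(lagged = true_temps, bias = bias), class = "sensor_state")
}

#' Advance the sensor lag filters
#'
#' Exact exponential update of the first-order lag over a plant substep.
#' Call once per substep with the current true temperatures.
#'
#' @param state A `sensor_state`.
#' @param true_temps True temperature per sensor, degC.
#' @param dt Substep size, s.
#' @param cfg The [sensor_config()].
#' @return Updated `sensor_state`.
#' @export
sensor_advance <- function(state, true_temps, dt, cfg) {
  a <- ifelse(cfg$lag_tau > 0, exp(-dt / cfg$lag_tau), 0)
  state$lagged <- a * state$lagged + (1 - a) * true_temps
  state
}

quantize_half_away <- function(x, resolution) {
  sign(x) * floor(abs(x) / resolution + 0.5) * resolution
}

#' Read the sensors
#'
#' `reading = quantize(lagged + bias + noise, resolution)`. Noise is drawn
#' from the current RNG stream (one draw per sensor per call), so readings
#' are deterministic under a fixed seed.
#'
#' The signal chain carries two versions of each reading: the conditioned
#' analog signal (`lagged + bias + noise`, what the controller's analog
#' input digitises at fine resolution) and the display reading quantised
#' to the probe resolution (what the logger records). [sensor_read()]
#' returns the display reading; the engine additionally feeds the analog
#' signal to the control law.
#'
#' @param state A `sensor_state` (lag filters already advanced).
#' @param cfg The [sensor_config()].
#' @return Named numeric vector of readings in degC.
#' @export
sensor_read <- function(state, cfg) {
  sensor_read_full(state, cfg)$display
}

# one noise draw, both signal-chain taps
sensor_read_full <- function(state, cfg) {
  n <- length(cfg$names)
  noise <- if (cfg$noise_sd > 0) stats::rnorm(n, 0, cfg$noise_sd) else numeric(n)
  analog <- state$lagged + state$bias + noise
  list(analog = stats::setNames(analog, cfg$names),
       display = stats::setNames(quantize_half_away(analog, cfg$resolution),
                                 cfg$names))
}

#' Sample sensors in one call (stateless convenience)
#'
#' Convenience wrapper for offline use: advances the lag over one interval
#' and reads. The engine drives [sensor_advance()] per plant substep and
#' [sensor_read()] per control step instead.
#'
#' @param true_temps True temperature per sensor, degC.
#' @param state A `sensor_state`.
#' @param cfg The [sensor_config()].
#' @param dt Interval since the last sample, s (default 1).
#' @return List with `readings` (named vector) and `state`.
#' @export
sensor_sample <- function(true_temps, state, cfg, dt = 1) {
  state <- sensor_advance(state, true_temps, dt, cfg)
  list(readings = sensor_read(state, cfg), state = state)
}
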