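#' Uniformly sampled temperature trace
#'
#' A `temperature_trace` is the universal currency of the package: a
#' uniformly sampled time--temperature series for one sensor or one spatial
#' location, in seconds and degrees Celsius.
#'
#' @param times Numeric vector of sample times in seconds. Must be strictly
#'   increasing with a constant step (relative tolerance 1e-9). Each sample
#'   is taken to represent the interval `[t_i, t_i + dt)` (left-rectangle
#'   convention, matching 1 s logging of a sample-and-hold controller).
#' @param temps Numeric vector of temperatures in degrees Celsius, same
#'   length as `times`, all finite.
#' @param label Sensor identifier (single string).
#'
#' @return An object of class `temperature_trace`: a list with elements
#'   `times`, `temps`, `label` and `step` (the sampling interval in s).
#' @export
#' @examples
#' tr <- temperature_trace(0:599, rep(44, 600), "MHT")
#' cem43(tr)  # 10 min at 44 C -> 20 equivalent minutes
temperature_trace <- function(times, temps, label = "sensor") {
  times <- as.numeric(times)
  temps <- as.numeric(temps)
  if (length(times) == 0L) {
    stop("temperature_trace: empty trace", call. = FALSE)
  }
  if (length(times) != length(temps)) {
    stop("temperature_trace: times and temps must have equal length", call. = FALSE)
  }
  if (!all(is.finite(times)) || !all(is.finite(temps))) {
    stop("temperature_trace: times and temps must be finite", call. = FALSE)
  }
  if (length(times) == 1L) {
    stop("temperature_trace: need at least 2 samples to define a step", call. = FALSE)
  }
  dt <- diff(times)
  step <- dt[1L]
  if (step <= 0 || any(abs(dt - step) > 1e-9 * max(abs(step), 1))) {
    stop("temperature_trace: times must be strictly increasing with uniform step",
         call. = FALSE)
  }
  structure(list(times = times, temps = temps,
                 label = as.character(label)[1L], step = step),
            class = "temperature_trace")
}

#' @export
print.temperature_trace <- function(x, ...) {
  cat(sprintf("<temperature_trace '%s': %d samples, step %g s, %.2f-%.2f degC>\n",
              x$label, length(x$times), x$step,
              min(x$temps), max(x$temps)))
  invisible(x)
}

as_trace <- function(x) {
  if (!inherits(x, "temperature_trace")) {
    stop("expected a temperature_trace object", call. = FALSE)
  }
  x
}

#' Thermal dose parameters
#'
#' Parameters of the cumulative-equivalent-minutes isoeffect model. Each
#' sample held for `dt` contributes `dt * R^(breakpoint - T)` equivalent
#' minutes at the breakpoint, with `R` switching at the breakpoint
#' (Sapareto--Dewey convention: R = 0.5 at or above 43 degC, R = 0.25
#' below). Samples colder than `floor_temp` contribute nothing, so baseline
#' body temperature does not accrue spurious dose; set `floor_temp = -Inf`
#' to integrate everything.
#'
#' @param breakpoint Breakpoint temperature in degC (default 43).
#' @param R_above R for samples at or above the breakpoint (default 0.5).
#' @param R_below R for samples below the breakpoint (default 0.25).
#' @param floor_temp Temperatures below this contribute zero dose
#'   (default 39 degC).
#' @return An object of class `dose_params`.
#' @export
dose_params <- function(breakpoint = 43, R_above = 0.5, R_below = 0.25,
                        floor_temp = 39) {
  stopifnot(is.numeric(breakpoint), length(breakpoint) == 1L, is.finite(breakpoint))
  if (!(R_below > 0 && R_below <= R_above && R_above < 1)) {
    stop("dose_params: need 0 < R_below <= R_above < 1", call. = FALSE)
  }
  if (!(floor_temp <= breakpoint)) {
    stop("dose_params: floor_temp must not exceed breakpoint", call. = FALSE)
  }
  structure(list(breakpoint = breakpoint, R_above = R_above,
                 R_below = R_below, floor_temp = floor_temp),
            class = "dose_params")
}

cem43_increments <- function(trace, params) {
  trace <- as_trace(trace)
  if (!inherits(params, "dose_params")) {
    stop("cem43: params must be a dose_params object", call. = FALSE)
  }
  temps <- trace$temps
  R <- ifelse(temps >= params$breakpoint, params$R_above, params$R_below)
  inc <- (trace$step / 60) * R ^ (params$breakpoint - temps)
  inc[temps < params$floor_temp] <- 0
  inc
}

#' Cumulative equivalent minutes at the breakpoint (CEM43)
#'
#' Converts a time--temperature history into the isoeffect dose in
#' equivalent minutes at the breakpoint temperature, by left-rectangle
#' summation over samples: `sum(dt_i * R^(breakpoint - T_i))`, in minutes.
#'
#' @param trace A [temperature_trace()].
#' @param params A [dose_params()] object.
#' @return Non-negative dose in equivalent minutes.
#' @export
#' @examples
#' # the canonical recipe: 44 degC held 30 min doubles to 60 equivalent min
#' tr <- temperature_trace(0:1799, rep(44, 1800), "MHT")
#' cem43(tr)
cem43 <- function(trace, params = dose_params()) {
  sum(cem43_increments(trace, params))
}

#' Running CEM43 dose series
#'
#' Cumulative dose after each sample, as a trace-shaped series; supports a
#' live dose display alongside a session log. The final element equals
#' [cem43()] of the whole trace and the series is non-decreasing.
#'
#' @inheritParams cem43
#' @return A list with `times` (s) and `dose_min` (cumulative minutes).
#' @export
cem43_running <- function(trace, params = dose_params()) {
  inc <- cem43_increments(trace, params)
  list(times = trace$times, dose_min = cumsum(inc))
}

#' Per-timepoint temperature percentile across traces
#'
#' Computes, at every time point, the given percentile of the temperature
#' distribution across several traces on an identical time grid (linear
#' interpolation between order statistics). With `percentile = 10` the
#' result is the temperature exceeded by 90% of the sensors/volume
#' elements, so `cem43()` of the result is the CEM43T90 dose descriptor.
#'
#' @param traces List of [temperature_trace()] objects on identical grids.
#' @param percentile Percentile in `[0, 100]`.
#' @return A [temperature_trace()] of the per-timepoint percentile.
#' @export
t_percentile_trace <- function(traces, percentile) {
  if (!is.list(traces) || length(traces) == 0L) {
    stop("t_percentile_trace: need a non-empty list of traces", call. = FALSE)
  }
  traces <- lapply(traces, as_trace)
  stopifnot(is.numeric(percentile), length(percentile) == 1L,
            percentile >= 0, percentile <= 100)
  ref <- traces[[1L]]$times
  for (tr in traces[-1L]) {
    if (length(tr$times) != length(ref) || any(abs(tr$times - ref) > 1e-9)) {
      stop("t_percentile_trace: traces are not on identical time grids",
           call. = FALSE)
    }
  }
  tm <- vapply(traces, function(tr) tr$temps, numeric(length(ref)))
  tm <- matrix(tm, nrow = length(ref))
  q <- apply(tm, 1L, stats::quantile, probs = percentile / 100,
             names = FALSE, type = 7)
  temperature_trace(ref, q, label = sprintf("p%g", percentile))
}
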