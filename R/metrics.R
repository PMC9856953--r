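#' Rise time of a step response
#'
#' First time the trace reaches 90% of the commanded step
#' (`T0 + 0.9 (T_ref - T0)`), linearly interpolated between samples.
#' The 90% criterion is the control-engineering standard; "first reach the
#' setpoint" is ill-posed for non-overshooting responses.
#'
#' @param trace A [temperature_trace()] starting at heating onset.
#' @param T_ref Setpoint, degC; must exceed `T0`.
#' @param T0 Baseline at onset, degC (default: first sample).
#' @param fraction Step fraction defining the rise (default 0.9).
#' @return Rise time in s, or `NA` (with attribute `reached = FALSE`) if
#'   the level is never reached.
#' @export
rise_time <- function(trace, T_ref, T0 = trace$temps[1L], fraction = 0.9) {
  trace <- as_trace(trace)
  if (!(T_ref > T0)) stop("rise_time: T_ref must exceed T0", call. = FALSE)
  level <- T0 + fraction * (T_ref - T0)
  idx <- which(trace$temps >= level)
  if (length(idx) == 0L) {
    return(structure(NA_real_, reached = FALSE))
  }
  i <- idx[1L]
  if (i == 1L) return(structure(trace$times[1L] - trace$times[1L], reached = TRUE))
  t0 <- trace$times[i - 1L]; t1 <- trace$times[i]
  y0 <- trace$temps[i - 1L]; y1 <- trace$temps[i]
  tc <- if (y1 == y0) t1 else t0 + (level - y0) / (y1 - y0) * (t1 - t0)
  structure(tc - trace$times[1L], reached = TRUE)
}

#' Settling time into a fixed band
#'
#' Earliest time after which the trace stays within `+/-band` of the
#' setpoint for all remaining samples; reported as the time of the last
#' sample outside the band (0 if the whole trace is inside).
#'
#' @param trace A [temperature_trace()].
#' @param T_ref Setpoint, degC.
#' @param band Band half-width, degC (default 0.5, the design criterion).
#' @return Settling time in s relative to the trace start, or `NA` (with
#'   attribute `settled = FALSE`) if the final sample is outside the band.
#' @export
settling_time <- function(trace, T_ref, band = 0.5) {
  trace <- as_trace(trace)
  outside <- abs(trace$temps - T_ref) > band
  if (!any(outside)) return(structure(0, settled = TRUE))
  last_out <- max(which(outside))
  if (last_out == length(trace$temps)) {
    return(structure(NA_real_, settled = FALSE))
  }
  structure(trace$times[last_out] - trace$times[1L], settled = TRUE)
}

#' Percentage overshoot
#'
#' `M_p = max(0, max(T) - T_ref) / (T_ref - T0) * 100`: the peak excursion
#' above the setpoint as a percentage of the commanded step, the standard
#' control definition (a 5% bound stays meaningful for small steps).
#'
#' @inheritParams rise_time
#' @return Overshoot in percent (>= 0).
#' @export
overshoot_pct <- function(trace, T_ref, T0 = trace$temps[1L]) {
  trace <- as_trace(trace)
  if (!(T_ref > T0)) stop("overshoot_pct: T_ref must exceed T0", call. = FALSE)
  max(0, max(trace$temps) - T_ref) / (T_ref - T0) * 100
}

#' Steady-state error
#'
#' Mean absolute deviation from the setpoint over the evaluation window:
#' the samples after settling, restricted to the last `window_frac` of the
#' session. Reported both in degC and as percent of the setpoint.
#'
#' @param trace A [temperature_trace()].
#' @param T_ref Setpoint, degC.
#' @param band Settling band used to locate the window, degC.
#' @param window_frac Fraction of the session forming the window
#'   (default 0.2, i.e. the last 20% of samples).
#' @return List with `abs_degC`, `pct` and `settled`; the errors are `NA`
#'   when the trace never settles.
#' @export
steady_state_error <- function(trace, T_ref, band = 0.5, window_frac = 0.2) {
  trace <- as_trace(trace)
  ts <- settling_time(trace, T_ref, band)
  if (!isTRUE(attr(ts, "settled"))) {
    return(list(abs_degC = NA_real_, pct = NA_real_, settled = FALSE))
  }
  t_rel <- trace$times - trace$times[1L]
  t_end <- t_rel[length(t_rel)]
  w <- t_rel >= max(as.numeric(ts), (1 - window_frac) * t_end)
  err <- abs(trace$temps[w] - T_ref)
  list(abs_degC = mean(err), pct = mean(err) / T_ref * 100, settled = TRUE)
}

#' Controller performance report for a session
#'
#' Assembles rise time, settling time, overshoot, steady-state error and
#' the CEM43 dose of the control-sensor trace from a session log, and
#' marks each treatment design criterion pass/fail: rise < 60 s,
#' overshoot < 5%, settling < 5 min, steady-state error < 1% of setpoint,
#' and session CEM43 within 60 +/- 5 min (the dose window is only
#' meaningful for hyperthermic setpoints and is reported regardless).
#'
#' @param log A session log data frame (from [run_closed_loop()] or
#'   [read_session()]).
#' @param scenario The [scenario()] that produced it (provides setpoint,
#'   baseline and control-sensor id). Alternatively supply `T_ref` and
#'   `T0` directly.
#' @param T_ref,T0 Setpoint and baseline, degC (defaults from `scenario`).
#' @param dose_target,dose_halfwidth Dose window, min (60 +/- 5).
#' @param params Dose parameters for the CEM43 column recomputation.
#' @return An object of class `performance_report` (a list).
#' @export
performance_report <- function(log, scenario = NULL,
                               T_ref = scenario$controller$setpoint,
                               T0 = NULL,
                               dose_target = 60, dose_halfwidth = 5,
                               params = dose_params()) {
  log_df <- as.data.frame(log)
  need <- c("t_s", "cem43_min")
  if (!all(need %in% names(log_df)) || nrow(log_df) < 2L) {
    stop("performance_report: incomplete session log", call. = FALSE)
  }
  ctrl <- if (!is.null(scenario)) scenario$control_sensor else
    sub("^T_", "", grep("^T_(?!true)", names(log_df), perl = TRUE, value = TRUE)[1L])
  col <- paste0("T_", ctrl)
  if (!col %in% names(log_df)) {
    stop("performance_report: control sensor column '", col, "' missing",
         call. = FALSE)
  }
  if (is.null(T0)) T0 <- log_df[[col]][1L]
  tr <- temperature_trace(log_df$t_s, log_df[[col]], ctrl)
  t_r <- rise_time(tr, T_ref, T0)
  t_ss <- settling_time(tr, T_ref)
  M_p <- overshoot_pct(tr, T_ref, T0)
  sse <- steady_state_error(tr, T_ref)
  dose <- cem43(tr, params)
  report <- list(
    control_sensor = ctrl, T_ref = T_ref, T0 = T0,
    t_r = as.numeric(t_r), rise_reached = isTRUE(attr(t_r, "reached")),
    t_ss = as.numeric(t_ss), settled = isTRUE(attr(t_ss, "settled")),
    M_p = M_p,
    ss_error_abs = sse$abs_degC, ss_error_pct = sse$pct,
    cem43 = dose,
    criteria_pass = c(
      rise_lt_60s = isTRUE(attr(t_r, "reached")) && as.numeric(t_r) < 60,
      overshoot_lt_5pct = M_p < 5,
      settling_lt_5min = isTRUE(attr(t_ss, "settled")) && as.numeric(t_ss) < 300,
      ss_error_lt_1pct = isTRUE(sse$settled) && sse$pct < 1,
      cem43_in_window = abs(dose - dose_target) <= dose_halfwidth
    ))
  class(report) <- "performance_report"
  report
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("<performance_report: sensor '%s', T_ref %.1f degC>\n",
              x$control_sensor, x$T_ref))
  cat(sprintf("  rise time     : %s\n",
              if (x$rise_reached) sprintf("%.1f s", x$t_r) else "not reached"))
  cat(sprintf("  settling time : %s\n",
              if (x$settled) sprintf("%.1f s", x$t_ss) else "not settled"))
  cat(sprintf("  overshoot     : %.2f %%\n", x$M_p))
  if (x$settled) {
    cat(sprintf("  ss error      : %.3f degC (%.3f %%)\n",
                x$ss_error_abs, x$ss_error_pct))
  }
  cat(sprintf("  CEM43         : %.1f min\n", x$cem43))
  pass <- x$criteria_pass
  cat("  criteria      :",
      paste(sprintf("%s=%s", names(pass), ifelse(pass, "PASS", "fail")),
            collapse = " "), "\n")
  invisible(x)
}
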