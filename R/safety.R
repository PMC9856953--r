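#' Safety supervisor configuration
#'
#' Per-sensor temperature thresholds with optional hysteresis. Typical
#' settings: 50 degC at the control region to stop runaway heating,
#' 40 degC at the tissue periphery, 45 degC subcutaneous and 40 degC
#' rectal (core) during an in vivo session. Comparison is inclusive: a
#' reading at its threshold trips the gate.
#'
#' @param thresholds Named numeric vector or list, sensor id -> degC.
#' @param deadband Hysteresis in degC: after a trip, power resumes only
#'   when every supervised reading is below `threshold - deadband`
#'   (default 0, i.e. resume as soon as readings fall below the limit).
#' @return An object of class `safety_config`.
#' @export
#' @examples
#' safety_config(c(MHT = 50, periphery = 40))
safety_config <- function(thresholds, deadband = 0) {
  thresholds <- unlist(thresholds)
  if (length(thresholds) == 0L || is.null(names(thresholds)) ||
      any(names(thresholds) == "")) {
    stop("safety_config: thresholds must be a named vector", call. = FALSE)
  }
  if (!all(is.finite(thresholds))) {
    stop("safety_config: thresholds must be finite", call. = FALSE)
  }
  stopifnot(deadband >= 0)
  structure(list(thresholds = thresholds, deadband = deadband),
            class = "safety_config")
}

#' Initial (power-allowed) gate state
#'
#' @return An object of class `gate_state` with power allowed, no tripping
#'   sensor and a zero trip counter.
#' @export
gate_init <- function() {
  structure(list(power_allowed = TRUE, tripped_by = NA_character_,
                 trip_count = 0L, fault = FALSE),
            class = "gate_state")
}

#' Supervise one set of readings
#'
#' Trips (denies power) when any supervised reading is at or above its
#' threshold; resumes automatically only when all supervised readings are
#' below `threshold - deadband`. A missing or non-finite reading for a
#' configured sensor is fail-safe: power is denied and the `fault` flag
#' set. The trip counter increments on each allowed-to-denied edge.
#'
#' @param readings Named numeric vector of readings, degC.
#' @param cfg A [safety_config()].
#' @param state A `gate_state` from [gate_init()] or a previous call.
#' @return Updated `gate_state`.
#' @export
supervise <- function(readings, cfg, state) {
  stopifnot(inherits(cfg, "safety_config"), inherits(state, "gate_state"))
  ids <- names(cfg$thresholds)
  vals <- readings[ids]
  was_allowed <- state$power_allowed
  if (any(!ids %in% names(readings)) || any(!is.finite(vals))) {
    state$fault <- TRUE
    state$power_allowed <- FALSE
    bad <- ids[!ids %in% names(readings) | !is.finite(vals)]
    state$tripped_by <- bad[1L]
    if (was_allowed) state$trip_count <- state$trip_count + 1L
    return(state)
  }
  state$fault <- FALSE
  over <- vals >= cfg$thresholds
  if (state$power_allowed) {
    if (any(over)) {
      state$power_allowed <- FALSE
      state$tripped_by <- ids[which(over)[1L]]
      state$trip_count <- state$trip_count + 1L
    }
  } else {
    clear <- vals < (cfg$thresholds - cfg$deadband)
    if (all(clear)) {
      state$power_allowed <- TRUE
      state$tripped_by <- NA_character_
    } else if (any(over)) {
      # still at/over the limit: keep the most recent offender on record
      state$tripped_by <- ids[which(over)[1L]]
    }
  }
  state
}
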