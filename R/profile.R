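# CBASS thermal-cycle profiles and hold-phase temperature summaries.
# A standard acute assay is a 7 h cycle: 3 h ramp from baseline to the target
# temperature, 3 h hold at the target, 1 h ramp back down, starting at 13:00
# local time. ED50 models use the *measured* mean hold-phase temperature of
# each tank rather than the programmed setpoint.

#' Build a CBASS thermal-cycle profile and its setpoint series
#'
#' @param baseline baseline temperature (degC), typically the local maximum
#'   monthly mean (MMM) climatology.
#' @param offset heat-hold offset above baseline (degC, >= 0); 0 gives the
#'   control profile (flat at baseline).
#' @param ramp_up,hold,ramp_down phase durations in hours (defaults 3, 3, 1).
#' @param start_clock_time "HH:MM" local start time (default "13:00").
#' @param resolution_min setpoint spacing in minutes.
#' @return A list of class `thermal_profile`: the phase durations, `baseline`,
#'   `target = baseline + offset`, `start_clock_time`, and `setpoints`, a
#'   tibble with `minute` (from cycle start) and `setpoint_c`. The series has
#'   `total_minutes / resolution + 1` rows, starts and ends at baseline, and
#'   sits at the target for the whole hold phase.
#' @export
#' @examples
#' p <- build_profile(30.5, 9)   # severe treatment: hold at 39.5 degC
#' range(p$setpoints$setpoint_c)
build_profile <- function(baseline, offset, ramp_up = 3, hold = 3,
                          ramp_down = 1, start_clock_time = "13:00",
                          resolution_min = 1) {
  check_number(baseline, "baseline", min = .Machine$double.eps)
  check_number(offset, "offset", min = 0)
  check_number(ramp_up, "ramp_up", min = 0)
  check_number(hold, "hold", min = 0)
  check_number(ramp_down, "ramp_down", min = 0)
  check_number(resolution_min, "resolution_min", min = 1e-9)
  target <- baseline + offset
  total_min <- (ramp_up + hold + ramp_down) * 60
  minute <- seq(0, total_min, by = resolution_min)
  up_end <- ramp_up * 60
  hold_end <- (ramp_up + hold) * 60
  setpoint <- ifelse(
    minute < up_end,
    baseline + (target - baseline) * (if (up_end > 0) minute / up_end else 0),
    ifelse(minute < hold_end, target,
           if (ramp_down > 0) {
             target - (target - baseline) * (minute - hold_end) / (ramp_down * 60)
           } else baseline))
  structure(
    list(baseline = baseline, target = target,
         ramp_up = ramp_up, hold = hold, ramp_down = ramp_down,
         start_clock_time = start_clock_time,
         setpoints = tibble::tibble(minute = minute, setpoint_c = setpoint)),
    class = "thermal_profile")
}

#' Mean measured temperature over the heat-hold phase
#'
#' Averages logger samples whose timestamps fall in the half-open hold window
#' `[start + ramp_up, start + ramp_up + hold)`. Used in lieu of the programmed
#' target temperature when fitting dose-response curves (e.g. a programmed
#' 36.5 degC tank that actually held at 37.0 degC enters the model as 37).
#'
#' @param log a tibble with columns `timestamp` (POSIXct, or numeric minutes
#'   from cycle start) and `temperature_c`.
#' @param profile a [build_profile()] object giving phase durations and the
#'   cycle start clock time.
#' @param start cycle start. If `NULL`: 0 for numeric timestamps, or the
#'   profile's `start_clock_time` on the date of the first sample for POSIXct.
#' @return The arithmetic mean hold-phase temperature (degC).
#' @export
hold_phase_mean <- function(log, profile, start = NULL) {
  check_columns(log, c("timestamp", "temperature_c"), "temperature log")
  ts <- log$timestamp
  if (inherits(ts, "POSIXct")) {
    if (is.null(start)) {
      day <- format(min(ts), "%Y-%m-%d")
      start <- as.POSIXct(paste(day, profile$start_clock_time),
                          tz = attr(ts, "tzone") %||% "UTC")
    }
    minutes <- as.numeric(difftime(ts, start, units = "mins"))
  } else {
    minutes <- as.numeric(ts) - (start %||% 0)
  }
  lo <- profile$ramp_up * 60
  hi <- (profile$ramp_up + profile$hold) * 60
  in_hold <- minutes >= lo & minutes < hi
  if (!any(in_hold)) {
    abort(sprintf("No logger samples in the hold window [%g, %g) minutes.",
                  lo, hi),
          class = "coralscreen_data_error")
  }
  mean(log$temperature_c[in_hold])
}
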