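#' Alarm generation settings
#'
#' @param ph_min prediction horizon in minutes (15, 20, 25 or 30): the
#'   forecast step compared against the alarm threshold.
#' @param alarm_level predictive triggering threshold in mg/dL. Distinct
#'   from the clinical hypoglycaemia threshold: it is a tuned
#'   hyperparameter and may sit below or above 54 mg/dL.
#' @param hypo_threshold clinical Level-2 hypoglycaemia threshold (mg/dL).
#' @param shutoff_min no new alarm is raised within this many minutes of a
#'   previous one; defaults to the prediction horizon.
#' @return an `alarm_config`.
#' @export
alarm_config <- function(ph_min = 25, alarm_level = 54, hypo_threshold = 54,
                         shutoff_min = ph_min) {
  stopifnot(ph_min %% 5 == 0, ph_min >= 5, ph_min <= 30, shutoff_min >= 0)
  structure(
    list(
      ph_min = ph_min, alarm_level = alarm_level,
      hypo_threshold = hypo_threshold, shutoff_min = shutoff_min
    ),
    class = "alarm_config"
  )
}

#' Generate predictive hypoglycaemia alarms from a forecast stream
#'
#' Walks each subject's forecast stream in time order and raises an alarm
#' at origin `t` iff all three hold:
#' \enumerate{
#'   \item the forecast at exactly the prediction horizon is below the
#'     triggering threshold: `yhat(t + PH | t) < alarm_level`;
#'   \item no previous alarm was raised within the shut-off window
#'     `(t - shutoff_min, t]`;
#'   \item the current CGM value at `t` is not already below the
#'     hypoglycaemia threshold (alarms are pointless once the subject is
#'     hypoglycaemic; suppression lifts as soon as glucose recovers to
#'     `>= hypo_threshold`).
#' }
#' Origins whose current sample is a held (zero-order-hold) value are
#' allowed to alarm — a real-time system must act on held values — and are
#' flagged in the output.
#'
#' @param forecasts forecast tibble from [forecast_stream()]; must contain
#'   the step `ph_min / 5`.
#' @param trace the [cgm_trace()] the forecasts were issued on.
#' @param config an [alarm_config()].
#' @return tibble of alarms: `subject_id`, `origin`, `time_min`,
#'   `predicted` (mg/dL at the horizon), `from_held` (logical).
#' @export
generate_alarms <- function(forecasts, trace, config) {
  assert_trace(trace)
  stopifnot(inherits(config, "alarm_config"))
  step_needed <- config$ph_min / trace_step(trace)
  if (nrow(forecasts) > 0 && max(forecasts$step) < step_needed) {
    stop(
      "forecast stream has only ", max(forecasts$step),
      " steps; PH = ", config$ph_min, " min needs step ", step_needed
    )
  }
  fc <- forecasts[forecasts$step == step_needed, , drop = FALSE]
  out <- list()
  for (id in unique(fc$subject_id)) {
    f <- dplyr::arrange(fc[fc$subject_id == id, , drop = FALSE], .data$time_min)
    tr <- trace[trace$subject_id == id, , drop = FALSE]
    y_now <- tr$glucose[match(f$origin, seq_len(nrow(tr)))]
    held <- tr$status[match(f$origin, seq_len(nrow(tr)))] == "zoh_filled"
    last_alarm <- -Inf
    keep <- logical(nrow(f))
    for (i in seq_len(nrow(f))) {
      if (is.na(f$predicted[i]) || f$predicted[i] >= config$alarm_level) next
      if (f$time_min[i] - last_alarm < config$shutoff_min) next
      if (is.na(y_now[i]) || y_now[i] < config$hypo_threshold) next
      keep[i] <- TRUE
      last_alarm <- f$time_min[i]
    }
    if (any(keep)) {
      out[[id]] <- tibble::tibble(
        subject_id = id,
        origin = f$origin[keep],
        time_min = f$time_min[keep],
        predicted = f$predicted[keep],
        from_held = held[keep] %in% TRUE
      )
    }
  }
  if (!length(out)) {
    return(tibble::tibble(
      subject_id = character(0), origin = integer(0), time_min = numeric(0),
      predicted = numeric(0), from_held = logical(0)
    ))
  }
  dplyr::bind_rows(out)
}
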