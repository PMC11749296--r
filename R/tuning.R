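#' Grid-search the prediction horizon and alarm threshold
#'
#' For every (PH, AlarmLevel) cell, regenerates alarms from the supplied
#' forecast stream, matches them against the trace's Level-2 episodes and
#' recomputes the event-based metrics; the best cell maximises F1. Run on
#' the validation split. Deterministic given its inputs.
#'
#' Ties on F1 are broken by (in order) lower FP/day, larger PH (more
#' warning time), then lower AlarmLevel — alarm burden first.
#'
#' @param forecasts forecast stream over the validation trace, with every
#'   step up to `max(ph_values)/5`.
#' @param trace the validation [cgm_trace()] (causally filled).
#' @param ph_values candidate horizons, minutes.
#' @param alarm_levels candidate triggering thresholds, mg/dL.
#' @param hypo_threshold clinical threshold used for episode extraction
#'   and alarm suppression.
#' @param window_min event-matching window, minutes.
#' @return a `pbh_tuning` tibble with one row per cell (`ph_min`,
#'   `alarm_level`, `precision`, `recall`, `f1`, `fp_per_day`,
#'   `tg_median_min`, `n_alarms`) and attribute `best` (the winning row).
#' @export
tune_alarms <- function(forecasts, trace, ph_values = c(15, 20, 25, 30),
                        alarm_levels = 35:80, hypo_threshold = 54,
                        window_min = 45) {
  assert_trace(trace)
  if (!length(ph_values) || !length(alarm_levels)) stop("empty tuning grid")
  stopifnot(all(ph_values %% 5 == 0), all(ph_values <= 30))
  step <- trace_step(trace)
  episodes <- detect_episodes(trace, threshold = hypo_threshold)
  days <- monitored_days(trace)
  cells <- tidyr::expand_grid(ph_min = sort(ph_values), alarm_level = sort(alarm_levels))
  rows <- purrr::pmap(cells, function(ph_min, alarm_level) {
    cfg <- alarm_config(
      ph_min = ph_min, alarm_level = alarm_level,
      hypo_threshold = hypo_threshold
    )
    alarms <- generate_alarms(forecasts, trace, cfg)
    m <- match_alarms(alarms, episodes, window_min = window_min, monitored_days = days)
    prf <- precision_recall_f1(m)
    tg <- time_gain_summary(m)
    tibble::tibble(
      ph_min = ph_min, alarm_level = alarm_level,
      precision = prf$precision, recall = prf$recall, f1 = prf$f1,
      fp_per_day = m$fp / days, tg_median_min = tg$median_min,
      n_alarms = m$n_alarms
    )
  })
  out <- dplyr::bind_rows(rows)
  ranked <- dplyr::arrange(
    out,
    dplyr::desc(.data$f1), .data$fp_per_day, dplyr::desc(.data$ph_min), .data$alarm_level
  )
  structure(out, best = ranked[1, ], class = c("pbh_tuning", class(out)))
}

#' Monitored time of a trace in days
#'
#' The calendar span of the grid, regardless of missingness — the
#' denominator for false alarms per day.
#'
#' @param trace a [cgm_trace()].
#' @return total days across all subjects.
#' @export
monitored_days <- function(trace) {
  step <- trace_step(trace)
  sum(dplyr::summarise(
    tibble::as_tibble(trace), n = dplyr::n(), .by = "subject_id"
  )$n) * step / 1440
}

#' Best cell of a tuning run
#' @param tuning a `pbh_tuning`.
#' @return one-row tibble (the F1-maximising cell after tie-breaks).
#' @export
best_cell <- function(tuning) {
  stopifnot(inherits(tuning, "pbh_tuning"))
  attr(tuning, "best")
}

#' @exportS3Method generics::glance
glance.pbh_tuning <- function(x, ...) {
  attr(x, "best")
}

#' @exportS3Method generics::tidy
tidy.pbh_tuning <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Precision-recall curve of a tuning run
#'
#' One curve per PH, points ordered by increasing AlarmLevel.
#'
#' @param tuning a `pbh_tuning`.
#' @return tibble `ph_min`, `alarm_level`, `precision`, `recall`.
#' @export
pr_curve <- function(tuning) {
  stopifnot(inherits(tuning, "pbh_tuning"))
  dplyr::select(
    dplyr::arrange(tibble::as_tibble(tuning), .data$ph_min, .data$alarm_level),
    "ph_min", "alarm_level", "precision", "recall"
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.pbh_tuning <- function(object, ...) {
  crv <- pr_curve(object)
  best <- attr(object, "best")
  ggplot2::ggplot(crv, ggplot2::aes(x = .data$recall, y = .data$precision,
                                    colour = factor(.data$ph_min))) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_point(
      data = best, colour = "red", shape = 17, size = 3,
      ggplot2::aes(x = .data$recall, y = .data$precision)
    ) +
    ggplot2::labs(
      x = "Recall (%)", y = "Precision (%)", colour = "PH (min)",
      title = "Alarm tuning: precision-recall by horizon"
    )
}
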