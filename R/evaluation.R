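#' Detect Level-2 hypoglycaemic episodes in a trace
#'
#' Finds maximal runs of consecutive samples strictly below `threshold`
#' (missing samples never count as below), merges runs separated by fewer
#' than `merge_gap_min` minutes of at-or-above-threshold samples, and
#' discards merged runs shorter than `min_duration_min`. The 15-min
#' minimum duration and merge gap follow the international CGM consensus
#' definition of a sensor hypoglycaemic event.
#'
#' @param trace a [cgm_trace()].
#' @param threshold episode threshold, mg/dL (54 = Level-2).
#' @param min_duration_min minimum episode duration, minutes.
#' @param merge_gap_min runs separated by less than this are merged.
#' @return tibble with one row per episode: `subject_id`, `onset`, `end`
#'   (1-based grid indices), `onset_min`, `end_min`, `duration_min`.
#' @export
detect_episodes <- function(trace, threshold = 54, min_duration_min = 15,
                            merge_gap_min = 15) {
  assert_trace(trace)
  step <- trace_step(trace)
  out <- list()
  for (id in unique(trace$subject_id)) {
    y <- trace$glucose[trace$subject_id == id]
    tm <- trace$time_min[trace$subject_id == id]
    low <- !is.na(y) & y < threshold
    runs <- run_bounds(low)
    if (nrow(runs) == 0) next
    # merge runs separated by < merge_gap_min of non-low samples
    if (nrow(runs) > 1) {
      merged <- runs[1, , drop = FALSE]
      for (i in 2:nrow(runs)) {
        gap <- (runs$start[i] - merged$end[nrow(merged)] - 1L) * step
        if (gap < merge_gap_min) {
          merged$end[nrow(merged)] <- runs$end[i]
        } else {
          merged <- rbind(merged, runs[i, , drop = FALSE])
        }
      }
      runs <- merged
    }
    dur <- (runs$end - runs$start + 1L) * step
    keep <- dur >= min_duration_min
    if (!any(keep)) next
    out[[id]] <- tibble::tibble(
      subject_id = id,
      onset = runs$start[keep], end = runs$end[keep],
      onset_min = tm[runs$start[keep]], end_min = tm[runs$end[keep]],
      duration_min = dur[keep]
    )
  }
  if (!length(out)) {
    return(tibble::tibble(
      subject_id = character(0), onset = integer(0), end = integer(0),
      onset_min = numeric(0), end_min = numeric(0), duration_min = numeric(0)
    ))
  }
  dplyr::bind_rows(out)
}

run_bounds <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Match alarms to hypoglycaemic episodes (event-based scoring)
#'
#' An alarm raised at time `s` is a true positive iff some episode onset
#' lies in `(s, s + window_min]`, otherwise a false positive. An episode
#' is detected iff some alarm lies in `[onset - window_min, onset)`;
#' undetected episodes are false negatives. The time gain of a detected
#' episode is the distance from its onset back to the earliest alarm in
#' its window. Note the deliberate asymmetry: true/false positives count
#' alarms, false negatives count events.
#'
#' Matching is per subject; counts and time gains are pooled.
#'
#' @param alarms alarm tibble from [generate_alarms()].
#' @param episodes episode tibble from [detect_episodes()].
#' @param window_min matching window, minutes.
#' @param monitored_days total monitored time in days (calendar span of
#'   the evaluated segments, regardless of missingness); used by
#'   [fp_per_day()].
#' @return an `alarm_match` object: counts `tp`, `fp`, `fn`, `detected`,
#'   the vector of per-event `time_gains` (minutes) and `monitored_days`.
#' @export
match_alarms <- function(alarms, episodes, window_min = 45, monitored_days = NA_real_) {
  tp <- 0L; fp <- 0L; fn <- 0L; detected <- 0L
  gains <- numeric(0)
  ids <- union(unique(alarms$subject_id), unique(episodes$subject_id))
  for (id in ids) {
    a <- sort(alarms$time_min[alarms$subject_id == id])
    o <- sort(episodes$onset_min[episodes$subject_id == id])
    for (s in a) {
      if (any(o > s & o <= s + window_min)) tp <- tp + 1L else fp <- fp + 1L
    }
    for (on in o) {
      in_win <- a[a >= on - window_min & a < on]
      if (length(in_win)) {
        detected <- detected + 1L
        gains <- c(gains, on - min(in_win))
      } else {
        fn <- fn + 1L
      }
    }
  }
  structure(
    list(
      tp = tp, fp = fp, fn = fn, detected = detected,
      n_alarms = tp + fp, n_events = detected + fn,
      time_gains = gains, window_min = window_min,
      monitored_days = monitored_days
    ),
    class = "alarm_match"
  )
}

#' @export
print.alarm_match <- function(x, ...) {
  cat(sprintf(
    "<alarm_match: %d alarms (%d TP / %d FP), %d events (%d detected / %d FN)>\n",
    x$n_alarms, x$tp, x$fp, x$n_events, x$detected, x$fn
  ))
  invisible(x)
}

#' Precision, recall and F1 from an alarm match
#'
#' Precision is alarm-wise (`100 * TP / (TP + FP)`); recall is event-wise
#' (`100 * detected / (detected + FN)`); F1 is the harmonic mean of the
#' two. Any zero-denominator case yields 0 with the corresponding
#' `*_undefined` flag set.
#'
#' @param match an `alarm_match`.
#' @return one-row tibble: `precision`, `recall`, `f1` (percent) plus
#'   logical `precision_undefined`, `recall_undefined`, `f1_undefined`.
#' @export
precision_recall_f1 <- function(match) {
  stopifnot(inherits(match, "alarm_match"))
  p_und <- match$n_alarms == 0
  r_und <- match$n_events == 0
  p <- if (p_und) 0 else 100 * match$tp / match$n_alarms
  r <- if (r_und) 0 else 100 * match$detected / match$n_events
  f_und <- (p + r) == 0
  f1 <- if (f_und) 0 else 2 * p * r / (p + r)
  tibble::tibble(
    precision = p, recall = r, f1 = f1,
    precision_undefined = p_und, recall_undefined = r_und, f1_undefined = f_und
  )
}

#' False alarms per monitored day
#'
#' @param match an `alarm_match` with `monitored_days` set.
#' @return false positives divided by monitored days.
#' @export
fp_per_day <- function(match) {
  stopifnot(inherits(match, "alarm_match"))
  if (is.na(match$monitored_days) || match$monitored_days <= 0) {
    stop("fp_per_day needs monitored_days > 0")
  }
  match$fp / match$monitored_days
}

#' Time-gain summary (median and quartiles)
#'
#' Nearest-rank (type-1) quantiles of the per-event time gains. With no
#' detected events the summary is undefined and returned as `NA`, not 0.
#'
#' @param match an `alarm_match`.
#' @return one-row tibble: `n`, `median_min`, `q25_min`, `q75_min`.
#' @export
time_gain_summary <- function(match) {
  stopifnot(inherits(match, "alarm_match"))
  g <- match$time_gains
  if (!length(g)) {
    return(tibble::tibble(n = 0L, median_min = NA_real_, q25_min = NA_real_, q75_min = NA_real_))
  }
  q <- stats::quantile(g, c(0.25, 0.5, 0.75), type = 1, names = FALSE)
  tibble::tibble(n = length(g), median_min = q[2], q25_min = q[1], q75_min = q[3])
}

#' @exportS3Method generics::glance
glance.alarm_match <- function(x, ...) {
  prf <- precision_recall_f1(x)
  tg <- time_gain_summary(x)
  tibble::tibble(
    precision = prf$precision, recall = prf$recall, f1 = prf$f1,
    fp_per_day = if (!is.na(x$monitored_days) && x$monitored_days > 0) x$fp / x$monitored_days else NA_real_,
    tg_median_min = tg$median_min, tg_q25_min = tg$q25_min, tg_q75_min = tg$q75_min,
    n_alarms = x$n_alarms, n_events = x$n_events
  )
}

#' @exportS3Method generics::tidy
tidy.alarm_match <- function(x, ...) {
  tibble::tibble(
    outcome = c("tp", "fp", "fn", "detected"),
    count = c(x$tp, x$fp, x$fn, x$detected)
  )
}

#' Mean absolute forecast error at a prediction horizon
#'
#' `mean(|y(t + PH) - yhat(t + PH | t)|)` over all forecast origins whose
#' target sample exists; origins whose target is missing are skipped.
#'
#' @param trace the actual [cgm_trace()].
#' @param forecasts forecast tibble from [forecast_stream()].
#' @param ph_min horizon in minutes; the step `ph_min / 5` must be present.
#' @param target_status which target sample statuses count as ground
#'   truth. The default accepts any non-missing sample (including held
#'   values, which is what a deployed system is scored against); restrict
#'   to `c("observed", "interpolated")` to score against measured samples
#'   only.
#' @return MAE in mg/dL.
#' @export
mae <- function(trace, forecasts, ph_min,
                target_status = c("observed", "interpolated", "zoh_filled")) {
  assert_trace(trace)
  k <- ph_min / trace_step(trace)
  fc <- forecasts[forecasts$step == k, , drop = FALSE]
  if (nrow(fc) == 0) stop("no forecasts at step ", k, " (PH = ", ph_min, " min)")
  errs <- numeric(0)
  for (id in unique(fc$subject_id)) {
    f <- fc[fc$subject_id == id, , drop = FALSE]
    tr <- trace[trace$subject_id == id, , drop = FALSE]
    tgt <- f$origin + k
    ok <- tgt <= nrow(tr)
    ok[ok] <- !is.na(tr$glucose[tgt[ok]]) & tr$status[tgt[ok]] %in% target_status
    errs <- c(errs, abs(tr$glucose[tgt[ok]] - f$predicted[ok]))
  }
  if (!length(errs)) stop("no valid forecast origins for MAE at PH = ", ph_min)
  mean(errs)
}

#' Per-subject glucometrics
#'
#' Standard CGM summary statistics over observed samples only: mean and
#' SD glucose, MAGE (mean amplitude of glycaemic excursions), time-in-range
#' percentages, and Level-2 episode count/durations (via
#' [detect_episodes()] at 54 mg/dL).
#'
#' MAGE follows the classic excursion algorithm: turning points are found
#' by a sign-change scan, sub-threshold oscillations are pruned, and MAGE
#' is the mean of the remaining peak-to-nadir amplitudes exceeding one SD
#' of the subject's trace.
#'
#' @param trace a [cgm_trace()].
#' @return tibble with one row per subject: `subject_id`, `n_days`,
#'   `mean_glucose`, `sd_glucose`, `mage`, `pct_below_54`, `pct_below_70`,
#'   `pct_70_180`, `pct_above_180`, `n_episodes`,
#'   `median_episode_duration_min`.
#' @export
glucometrics <- function(trace) {
  assert_trace(trace)
  step <- trace_step(trace)
  eps <- detect_episodes(trace)
  rows <- lapply(unique(trace$subject_id), function(id) {
    df <- trace[trace$subject_id == id, , drop = FALSE]
    y <- df$glucose[df$status == "observed"]
    if (length(y) * step < 1440) {
      warning("subject ", id, " has under one day of observed data")
    }
    e <- eps[eps$subject_id == id, , drop = FALSE]
    tibble::tibble(
      subject_id = id,
      n_days = nrow(df) * step / 1440,
      mean_glucose = mean(y),
      sd_glucose = stats::sd(y),
      mage = mage(y),
      pct_below_54 = 100 * mean(y < 54),
      pct_below_70 = 100 * mean(y < 70),
      pct_70_180 = 100 * mean(y >= 70 & y <= 180),
      pct_above_180 = 100 * mean(y > 180),
      n_episodes = nrow(e),
      median_episode_duration_min = if (nrow(e)) stats::median(e$duration_min) else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' Mean amplitude of glycaemic excursions
#'
#' @param y numeric glucose series (one subject, time order, no NAs).
#' @return MAGE in mg/dL; 0 when no excursion exceeds one SD.
#' @export
mage <- function(y) {
  y <- y[!is.na(y)]
  if (length(y) < 3) return(0)
  s <- stats::sd(y)
  if (s == 0) return(0)
  tp <- turning_values(y)
  # prune sub-SD oscillations: repeatedly drop the smallest swing
  repeat {
    if (length(tp) < 2) return(0)
    d <- abs(diff(tp))
    if (min(d) > s) break
    i <- which.min(d)
    if (i == 1) {
      tp <- tp[-1]
    } else if (i == length(d)) {
      tp <- tp[-length(tp)]
    } else {
      tp <- tp[-c(i, i + 1)]
    }
  }
  amps <- abs(diff(tp))
  mean(amps[amps > s])
}

# values at local extrema (including endpoints); plateaus collapse to one
turning_values <- function(y) {
  dedup <- y[c(TRUE, diff(y) != 0)]
  if (length(dedup) < 3) return(dedup)
  sgn <- sign(diff(dedup))
  turns <- which(diff(sgn) != 0) + 1L
  dedup[c(1L, turns, length(dedup))]
}
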