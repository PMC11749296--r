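#' Stream multi-step forecasts over a trace
#'
#' Simulates real-time acquisition: walks each subject's trace left to
#' right and, at every grid index where the model's history requirement is
#' met, issues a forecast of the next `steps` samples using only data at
#' or before that index. For the rAR model the coefficient update happens
#' in the same pass (run-to-run adaptation): the state absorbs each new
#' sample, then forecasts from it.
#'
#' @param model a fitted forecaster: [rar_model()], `arima_pem`,
#'   `windowed_fit`, or [clairvoyant_model()].
#' @param trace a causally filled [cgm_trace()].
#' @param steps forecast steps (1..6; 6 = 30-min horizon).
#' @param ... method-specific options.
#' @return tibble with columns `subject_id`, `origin` (1-based grid index
#'   of the forecast origin within the subject), `time_min`, `step`
#'   (1..steps) and `predicted` (mg/dL); one row per origin-step.
#' @export
forecast_stream <- function(model, trace, steps = 6, ...) {
  UseMethod("forecast_stream")
}

forecast_tibble <- function(subject_id, origins, time_min, pred_matrix) {
  steps <- ncol(pred_matrix)
  tibble::tibble(
    subject_id = rep(subject_id, length.out = length(origins) * steps),
    origin = rep(origins, each = steps),
    time_min = rep(time_min, each = steps),
    step = rep(seq_len(steps), times = length(origins)),
    predicted = as.numeric(t(pred_matrix))
  )
}

#' @rdname forecast_stream
#' @param reset_gap_min rAR only: the adaptive state is re-initialised
#'   after a missing run of at least this many minutes.
#' @export
forecast_stream.rar_model <- function(model, trace, steps = 6, reset_gap_min = 30, ...) {
  assert_trace(trace)
  step_min <- trace_step(trace)
  reset_slots <- ceiling(reset_gap_min / step_min)
  out <- list()
  for (id in unique(trace$subject_id)) {
    y <- trace$glucose[trace$subject_id == id]
    tm <- trace$time_min[trace$subject_id == id]
    st <- rar_reset(model)
    gap_run <- 0L
    origins <- integer(0); preds <- list()
    for (t in seq_along(y)) {
      if (is.na(y[t])) {
        gap_run <- gap_run + 1L
        if (gap_run >= reset_slots) st <- rar_reset(st)
        next
      }
      if (t > 1 && !is.na(y[t - 1])) {
        st <- rar_update(st, y[t - 1], y[t])
      }
      gap_run <- 0L
      if (st$n_updates >= st$burn_in) {
        origins <- c(origins, t)
        preds[[length(preds) + 1L]] <- st$a^seq_len(steps) * y[t]
      }
    }
    if (length(origins)) {
      out[[id]] <- forecast_tibble(id, origins, tm[origins], do.call(rbind, preds))
    }
  }
  dplyr::bind_rows(out)
}

#' @rdname forecast_stream
#' @export
forecast_stream.arima_pem <- function(model, trace, steps = 6, ...) {
  assert_trace(trace)
  p <- model$order[["p"]]; d <- model$order[["d"]]; q <- model$order[["q"]]
  if (d > 1) stop("forecast_stream supports d <= 1")
  min_hist <- p + d + q + 1L
  out <- list()
  for (id in unique(trace$subject_id)) {
    y <- trace$glucose[trace$subject_id == id]
    tm <- trace$time_min[trace$subject_id == id]
    r <- rle(!is.na(y))
    seg_end <- cumsum(r$lengths)
    seg_start <- seg_end - r$lengths + 1L
    for (s in seq_along(r$lengths)) {
      if (!r$values[s] || r$lengths[s] < min_hist) next
      ys <- y[seg_start[s]:seg_end[s]]
      fc <- arima_segment_forecasts(model, ys, steps, min_hist)
      if (is.null(fc)) next
      origins <- seg_start[s] + fc$pos - 1L
      out[[length(out) + 1L]] <- forecast_tibble(id, origins, tm[origins], fc$pred)
    }
  }
  dplyr::bind_rows(out)
}

# Vectorised iterated forecasts at every eligible origin of one contiguous
# segment. pos: 1-based positions within the segment.
arima_segment_forecasts <- function(model, ys, steps, min_hist) {
  p <- model$order[["p"]]; d <- model$order[["d"]]; q <- model$order[["q"]]
  L <- length(ys)
  pos <- seq.int(min_hist, L)
  if (!length(pos)) return(NULL)
  level <- model_level(model)
  w <- diff_d(ys, d)                       # length L - d
  if (d == 0) w <- w - level
  e <- css_residuals(w, model$phi, model$theta)
  e_full <- c(rep(0, p), e)                # aligned with w
  iw <- pos - d                            # origin index into w
  Wf <- matrix(0, length(pos), steps)
  for (k in seq_len(steps)) {
    acc <- rep(0, length(pos))
    if (p > 0) for (m in seq_len(p)) {
      acc <- acc + model$phi[m] * if (k - m >= 1) Wf[, k - m] else w[iw + k - m]
    }
    if (q > 0) for (j in seq_len(q)) {
      if (j >= k) acc <- acc + model$theta[j] * e_full[iw + k - j]
    }
    Wf[, k] <- acc
  }
  pred <- if (d == 1) {
    ys[pos] + t(apply(Wf, 1, cumsum))
  } else {
    Wf + level
  }
  if (steps == 1) pred <- matrix(pred, ncol = 1)
  list(pos = pos, pred = pred)
}

#' @rdname forecast_stream
#' @export
forecast_stream.windowed_fit <- function(model, trace, steps = 6, ...) {
  assert_trace(trace)
  w <- model$spec$input_window
  stopifnot(steps <= model$spec$output_steps)
  out <- list()
  for (id in unique(trace$subject_id)) {
    y <- trace$glucose[trace$subject_id == id]
    tm <- trace$time_min[trace$subject_id == id]
    if (length(y) < w) next
    ok <- ok_window(!is.na(y), w)
    origins <- which(ok) + w - 1L
    if (!length(origins)) next
    x <- t(vapply(origins, function(o) y[(o - w + 1):o], numeric(w)))
    pred <- stats::predict(model, x)[, seq_len(steps), drop = FALSE]
    out[[id]] <- forecast_tibble(id, origins, tm[origins], pred)
  }
  dplyr::bind_rows(out)
}
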