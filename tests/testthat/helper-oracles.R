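# Independent brute-force oracles used across test files. Each one
# restates the definition directly (loops and explicit sums), never
# calling the implementation path it checks.

# Exponentially-weighted least-squares AR(1) coefficient after the first
# t pairs of y, by direct summation. Includes the ridge prior implied by
# the recursion's initialisation (a0, p0); with prior = FALSE returns the
# plain weighted LS ratio.
batch_wrls <- function(y, t, mu, a0 = 1, p0 = 1e3, prior = TRUE) {
  i <- 2:t                       # pairs (y[i-1], y[i]), i = 2..t
  wts <- mu^(t - i)
  sxy <- sum(wts * y[i - 1] * y[i])
  sxx <- sum(wts * y[i - 1]^2)
  if (prior) {
    c0 <- mu^(t - 1) / p0
    (sxy + c0 * a0) / (sxx + c0)
  } else {
    sxy / sxx
  }
}

# Run the rAR recursion over y and return the coefficient after every
# update (one entry per pair).
rar_trajectory <- function(y, mu, a0 = 1, p0 = 1e3) {
  m <- rar_model(mu = mu, a0 = a0, p0 = p0, burn_in = 0)
  a <- numeric(length(y) - 1)
  for (t in 2:length(y)) {
    m <- rar_update(m, y[t - 1], y[t])
    a[t - 1] <- m$a
  }
  a
}

# Direct replay of the alarm rule over a single-subject forecast stream.
replay_alarms <- function(forecasts, trace, cfg) {
  k <- cfg$ph_min / 5
  f <- forecasts[forecasts$step == k, ]
  f <- f[order(f$time_min), ]
  y <- trace$glucose
  raised <- numeric(0)
  rows <- integer(0)
  for (i in seq_len(nrow(f))) {
    t <- f$time_min[i]
    y_now <- y[f$origin[i]]
    cond_a <- !is.na(f$predicted[i]) && f$predicted[i] < cfg$alarm_level
    cond_b <- !any(raised > t - cfg$shutoff_min & raised <= t)
    cond_c <- !is.na(y_now) && y_now >= cfg$hypo_threshold
    if (cond_a && cond_b && cond_c) {
      raised <- c(raised, t)
      rows <- c(rows, i)
    }
  }
  f$time_min[rows]
}

# Exhaustive pairwise event matcher on alarm times / onset times (single
# subject, minutes).
brute_match <- function(alarm_t, onset_t, window = 45) {
  tp <- 0L; fp <- 0L
  for (s in alarm_t) {
    hit <- FALSE
    for (o in onset_t) if (o > s && o <= s + window) hit <- TRUE
    if (hit) tp <- tp + 1L else fp <- fp + 1L
  }
  fn <- 0L; gains <- numeric(0)
  for (o in onset_t) {
    pre <- alarm_t[alarm_t >= o - window & alarm_t < o]
    if (length(pre) == 0) fn <- fn + 1L else gains <- c(gains, o - min(pre))
  }
  list(tp = tp, fp = fp, fn = fn, detected = length(onset_t) - fn, gains = gains)
}

# MAE by its definition loop.
mae_loop <- function(trace, forecasts, ph_min) {
  k <- ph_min / 5
  f <- forecasts[forecasts$step == k, ]
  tot <- 0; n <- 0
  for (i in seq_len(nrow(f))) {
    tr <- trace[trace$subject_id == f$subject_id[i], ]
    tgt <- f$origin[i] + k
    if (tgt > nrow(tr)) next
    if (is.na(tr$glucose[tgt])) next
    tot <- tot + abs(tr$glucose[tgt] - f$predicted[i])
    n <- n + 1
  }
  tot / n
}

# A fully observed single-subject trace from a numeric vector.
make_trace <- function(values, id = "S1", status = NULL) {
  cgm_trace(id, values, status)
}

# Noise-free, gap-free simulator settings for deterministic scenarios;
# callers may still override any field.
quiet_config <- function(...) {
  args <- utils::modifyList(
    list(noise_sd = 0, basal_sd = 0, gap_rate = 0),
    list(...)
  )
  do.call(sim_config, args)
}
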