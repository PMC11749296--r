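low_trace <- function(pattern, id = "S1") {
  # pattern: character vector of "L" (45 mg/dL), "H" (100), "N" (NA)
  v <- vapply(pattern, function(p) switch(p, L = 45, H = 100, N = NA_real_), numeric(1))
  make_trace(unname(v), id = id)
}

test_that("episodes follow the run / merge / minimum-duration rules", {
  # 5 consecutive low samples -> one 25-min episode
  e <- detect_episodes(low_trace(c("H", rep("L", 5), "H")))
  expect_equal(nrow(e), 1L)
  expect_equal(e$duration_min, 25)
  expect_equal(e$onset, 2L)

  # 10 min below threshold is too short
  none <- detect_episodes(low_trace(c("H", "L", "L", "H")))
  expect_equal(nrow(none), 0L)

  # two 15-min runs separated by one >= threshold sample merge
  merged <- detect_episodes(low_trace(c(rep("L", 3), "H", rep("L", 3))))
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$duration_min, 35)

  # missing samples never count as below threshold
  gap <- detect_episodes(low_trace(c("H", "N", "N", "N", "H")))
  expect_equal(nrow(gap), 0L)
})

test_that("episode detection ignores flanking normoglycaemia", {
  core <- c("H", rep("L", 4), "H")
  a <- detect_episodes(low_trace(core))
  b <- detect_episodes(low_trace(c(rep("H", 20), core, rep("H", 30))))
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$duration_min, b$duration_min)
})

alarm_tbl <- function(times, id = "S1") {
  tibble::tibble(
    subject_id = id, origin = as.integer(times / 5 + 1),
    time_min = times, predicted = 40, from_held = FALSE
  )
}

episode_tbl <- function(onsets, id = "S1") {
  tibble::tibble(
    subject_id = id, onset = as.integer(onsets / 5 + 1),
    end = as.integer(onsets / 5 + 4), onset_min = onsets,
    end_min = onsets + 15, duration_min = 20
  )
}

test_that("matching implements the 45-min window rules", {
  m <- match_alarms(alarm_tbl(600), episode_tbl(630))
  expect_equal(m$tp, 1L)
  expect_equal(m$time_gains, 30)

  far <- match_alarms(alarm_tbl(600), episode_tbl(650))
  expect_equal(far$fp, 1L)
  expect_equal(far$fn, 1L)

  miss <- match_alarms(alarm_tbl(numeric(0)), episode_tbl(630))
  expect_equal(miss$fn, 1L)

  # an alarm exactly at onset is too late; the window is (s, s + 45]
  late <- match_alarms(alarm_tbl(630), episode_tbl(630))
  expect_equal(late$tp, 0L)
  # an alarm exactly 45 min before the onset still counts
  edge <- match_alarms(alarm_tbl(585), episode_tbl(630))
  expect_equal(edge$tp, 1L)
  expect_equal(edge$time_gains, 45)
})

test_that("matching never crosses subjects", {
  a <- alarm_tbl(600, id = "A")
  e <- episode_tbl(630, id = "B")
  m <- match_alarms(a, e)
  expect_equal(m$fp, 1L)
  expect_equal(m$fn, 1L)
})

test_that("matching equals the exhaustive brute-force matcher", {
  withr::with_seed(61, {
    for (rep in 1:300) {
      a_t <- sort(sample(seq(0, 1400, by = 5), sample(0:10, 1)))
      o_t <- sort(sample(seq(0, 1400, by = 5), sample(0:5, 1)))
      m <- match_alarms(alarm_tbl(a_t), episode_tbl(o_t))
      o <- brute_match(a_t, o_t)
      expect_equal(m$tp, o$tp)
      expect_equal(m$fp, o$fp)
      expect_equal(m$fn, o$fn)
      expect_equal(sort(m$time_gains), sort(o$gains))
      expect_true(all(m$time_gains > 0 & m$time_gains <= 45))
    }
  })
})

test_that("precision, recall and F1 reproduce the harmonic-mean identity", {
  m <- structure(
    list(tp = 0L, fp = 0L, fn = 0L, detected = 0L, n_alarms = 0L,
         n_events = 0L, time_gains = numeric(0), monitored_days = 1),
    class = "alarm_match"
  )
  z <- precision_recall_f1(m)
  expect_equal(z$f1, 0)
  expect_true(z$precision_undefined)

  mk <- function(tp, fp, det, fn) {
    structure(
      list(tp = tp, fp = fp, fn = fn, detected = det, n_alarms = tp + fp,
           n_events = det + fn, time_gains = numeric(0), monitored_days = 1),
      class = "alarm_match"
    )
  }
  even <- precision_recall_f1(mk(1, 1, 1, 1))
  expect_equal(even$precision, 50)
  expect_equal(even$f1, 50)

  # F1 never exceeds the arithmetic mean of precision and recall
  withr::with_seed(62, {
    for (i in 1:50) {
      r <- precision_recall_f1(mk(sample(0:20, 1), sample(0:20, 1),
                                  sample(0:20, 1), sample(0:20, 1)))
      expect_true(all(c(r$precision, r$recall, r$f1) >= 0))
      expect_true(all(c(r$precision, r$recall, r$f1) <= 100))
      expect_lte(r$f1, (r$precision + r$recall) / 2 + 1e-12)
    }
  })
})

test_that("false alarms per day divide by the monitored span", {
  m <- match_alarms(alarm_tbl(600), episode_tbl(700), monitored_days = 6)
  expect_equal(fp_per_day(m), 1 / 6, tolerance = 1e-12)
  expect_error(fp_per_day(match_alarms(alarm_tbl(600), episode_tbl(630))), "monitored_days")
  # a rate of 0.17/day is one false alarm roughly every 6 days
  expect_equal(round(1 / 0.17), 6)
})

test_that("time gains summarise by nearest-rank quartiles", {
  m <- list(time_gains = c(5, 10, 15))
  class(m) <- "alarm_match"
  s <- time_gain_summary(m)
  expect_equal(c(s$median_min, s$q25_min, s$q75_min), c(10, 5, 15))

  one <- structure(list(time_gains = 20), class = "alarm_match")
  s1 <- time_gain_summary(one)
  expect_equal(c(s1$median_min, s1$q25_min, s1$q75_min), c(20, 20, 20))

  none <- structure(list(time_gains = numeric(0)), class = "alarm_match")
  expect_true(is.na(time_gain_summary(none)$median_min))

  withr::with_seed(63, {
    g <- sample(1:45, 20, replace = TRUE)
    st <- sort(g)
    s2 <- time_gain_summary(structure(list(time_gains = g), class = "alarm_match"))
    expect_equal(s2$q25_min, st[ceiling(0.25 * 20)])
    expect_equal(s2$median_min, st[ceiling(0.5 * 20)])
    expect_equal(s2$q75_min, st[ceiling(0.75 * 20)])
  })
})

test_that("MAE matches its definition loop and closed forms", {
  tr <- make_trace(seq(100, by = 1, length.out = 40))
  fc <- forecast_stream(clairvoyant_model(), tr)
  expect_equal(mae(tr, fc, 25), 0)
  fc_off <- dplyr::mutate(fc, predicted = .data$predicted + 7)
  expect_equal(mae(tr, fc_off, 25), 7)

  withr::with_seed(64, {
    tr2 <- make_trace(runif(60, 70, 200))
    fc2 <- forecast_stream(rar_model(), tr2)
    fc2$predicted <- fc2$predicted + rnorm(nrow(fc2))
    expect_equal(mae(tr2, fc2, 15), mae_loop(tr2, fc2, 15), tolerance = 1e-12)
  })
})

test_that("MAE skips origins whose target sample is missing", {
  y <- seq(100, by = 1, length.out = 30)
  tr <- make_trace(y)
  fc <- forecast_stream(clairvoyant_model(), tr)
  y2 <- y; y2[20] <- NA
  tr2 <- make_trace(y2)
  # only origins with surviving targets are scored; all are exact
  expect_equal(mae(tr2, fc, 25), 0)
  expect_error(mae(make_trace(rep(NA_real_, 10), status = rep("missing", 10)), fc, 25), "no valid")
})

test_that("glucometrics reproduce hand-computed summaries", {
  const <- glucometrics(make_trace(rep(100, 300)))
  expect_equal(const$sd_glucose, 0)
  expect_equal(const$mage, 0)
  expect_equal(const$pct_70_180, 100)
  expect_equal(const$n_episodes, 0L)

  sq <- rep(c(rep(80, 6), rep(160, 6)), 25)
  g <- glucometrics(make_trace(sq))
  expect_equal(g$mean_glucose, 120)
  expect_equal(g$pct_70_180, 100)
  expect_equal(g$mage, 80)
  expect_lt(g$sd_glucose, 80)
})

test_that("MAGE counts only excursions exceeding one SD", {
  sq <- rep(c(rep(80, 6), rep(160, 6)), 25)
  expect_equal(mage(sq), 80)
  # small ripples on the plateaus do not contribute
  withr::with_seed(65, ripple <- sq + runif(length(sq), -2, 2))
  expect_equal(mage(ripple), 80, tolerance = 0.1)
  expect_equal(mage(rep(5, 100) * 0 + 100), 0)
})
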