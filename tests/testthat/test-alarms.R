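# hand-built forecast stream: one subject, chosen predictions at PH = 25
# (step 5), benign values at other steps
manual_stream <- function(pred_at_ph, at_step = 5L) {
  n <- length(pred_at_ph)
  # vapply gives a steps x origins matrix; column-major flattening is
  # origin-major order, matching the tibble layout below
  pred <- as.numeric(vapply(
    pred_at_ph,
    function(p) ifelse(1:6 == at_step, p, 150),
    numeric(6)
  ))
  tibble::tibble(
    subject_id = "S1",
    origin = rep(seq_len(n), each = 6),
    time_min = rep((seq_len(n) - 1) * 5, each = 6),
    step = rep(1:6, n),
    predicted = pred
  )
}

test_that("an alarm fires when all three conditions hold", {
  tr <- make_trace(rep(80, 10))
  fc <- manual_stream(c(150, 150, 40, 150, 150, 150, 150, 150, 150, 150))
  al <- generate_alarms(fc, tr, alarm_config(ph_min = 25, alarm_level = 42))
  expect_equal(al$origin, 3L)
  expect_equal(al$predicted, 40)
  expect_false(al$from_held)
})

test_that("the shut-off suppresses re-triggers within the horizon", {
  tr <- make_trace(rep(80, 10))
  # triggers at origins 3 and 5 (10 min apart); PH = 25 -> second suppressed
  fc <- manual_stream(c(150, 150, 40, 150, 41, 150, 150, 150, 150, 39))
  al <- generate_alarms(fc, tr, alarm_config(ph_min = 25, alarm_level = 42))
  expect_equal(al$origin, c(3L, 10L))  # origin 10 is 35 min later: allowed
})

test_that("alarms are suppressed while glucose is already hypoglycaemic", {
  y <- rep(80, 10); y[3] <- 50
  fc <- manual_stream(rep(40, 10))
  # shut-off disabled so the hypoglycaemia condition acts alone
  cfg <- alarm_config(ph_min = 25, alarm_level = 42, shutoff_min = 0)
  al <- generate_alarms(fc, make_trace(y), cfg)
  expect_equal(al$origin, setdiff(1:10, 3L))  # suppression lifts on recovery
})

test_that("threshold comparison is strict and extremes behave", {
  tr <- make_trace(rep(80, 10))
  fc <- manual_stream(rep(42, 10))
  none <- generate_alarms(fc, tr, alarm_config(25, alarm_level = 42))
  expect_equal(nrow(none), 0L)  # predicted == level does not trigger

  empty <- generate_alarms(manual_stream(rep(100, 10)), tr, alarm_config(25, alarm_level = 20.001))
  expect_equal(nrow(empty), 0L)

  # saturating threshold with persistence forecasts: one alarm per shut-off window
  sat <- generate_alarms(manual_stream(rep(41, 40)), make_trace(rep(80, 40)),
                         alarm_config(25, alarm_level = 500))
  expect_true(all(diff(sat$time_min) >= 25))
  expect_equal(nrow(sat), sum(seq(0, 39 * 5, by = 5) %% 25 == 0))
})

test_that("short forecast streams are rejected for the requested horizon", {
  fc <- manual_stream(rep(100, 5))
  fc <- fc[fc$step <= 3, ]
  expect_error(
    generate_alarms(fc, make_trace(rep(80, 5)), alarm_config(ph_min = 25, alarm_level = 54)),
    "needs step 5"
  )
})

test_that("alarms from held samples are flagged", {
  y <- c(rep(80, 5), NA, NA, rep(80, 3))
  tr <- causal_fill(make_trace(y))
  fc <- manual_stream(c(rep(150, 5), 40, rep(150, 4)))
  al <- generate_alarms(fc, tr, alarm_config(25, 54))
  expect_equal(al$origin, 6L)
  expect_true(al$from_held)
})

test_that("generate_alarms equals the direct rule replay on random streams", {
  withr::with_seed(51, {
    for (rep in 1:100) {
      n <- 120
      y <- runif(n, 45, 180)
      tr <- make_trace(y)
      fc <- manual_stream(runif(n, 30, 90))
      cfg <- alarm_config(
        ph_min = sample(c(15, 20, 25, 30), 1),
        alarm_level = sample(35:80, 1)
      )
      fc2 <- fc
      fc2$predicted[fc2$step == 5] <- 150
      fc2$predicted[fc2$step == cfg$ph_min / 5] <- fc$predicted[fc$step == 5]
      al <- generate_alarms(fc2, tr, cfg)
      expect_identical(al$time_min, replay_alarms(fc2, tr, cfg))
    }
  })
})

test_that("the alarm set never depends on future samples", {
  withr::with_seed(52, {
    y <- runif(60, 45, 170)
    tr <- make_trace(y)
    fc <- manual_stream(runif(60, 30, 80))
    cfg <- alarm_config(25, 54)
    base <- generate_alarms(fc, tr, cfg)
    cut <- 30L
    y2 <- y; y2[(cut + 1):60] <- 400
    al2 <- generate_alarms(fc[fc$origin <= cut, ], make_trace(y2), cfg)
    expect_identical(al2, base[base$origin <= cut, ])
  })
})

test_that("no alarm coincides with concurrent hypoglycaemia and spacing holds", {
  withr::with_seed(53, {
    y <- runif(200, 45, 120)
    tr <- make_trace(y)
    fc <- manual_stream(runif(200, 30, 90))
    cfg <- alarm_config(20, 60)
    al <- generate_alarms(fc, tr, cfg)
    expect_true(all(y[al$origin] >= 54))
    if (nrow(al) > 1) expect_true(all(diff(al$time_min) >= cfg$shutoff_min))
  })
})
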